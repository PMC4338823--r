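id	consensus	width	type	evalue
1	CCAGGCTGGAGTGCAGTGGCGCAATCTCA	29	non-palindromic	1E-126
2	GGATTACAGGCGTGAGCCACCGCGCCTGG	29	non-palindromic	3.60E-123
3	GAGGTGCTGGGATTATAGGGG	21	non-palindromic	8.50E-35
4	CCTGACCTCATGAGA	15	non-palindromic	4.10E-22
5	AGACATGGAACCAACCTAAATGCCCACCA	29	non-palindromic	9.40E-17
6	AGGAGGCAAAGGAAG	15	non-palindromic	7.00E-11
7	TGGGATTGCAGGCAT	15	non-palindromic	1.20E-06
8	TTTCATGGCTGCATAGTATTCTATTGTGT	29	non-palindromic	1.00E-05
9	TGTAAATTAGTACAGCCTTTATGGAAAAC	29	non-palindromic	2.90E-12
10	AGTCCCAGCTTCTCGAGAAGCTGGGACT	28	palindromic	2.7E-97
11	TGCACCCCAGGCTGGGGTGCA	21	palindromic	8.4E-50
12	CTTGTACTCCCAACATGTTGGGAGTACAAG	30	palindromic	5.2E-72
13	CTTGAACCTCGGAGGTTCAAG	21	palindromic	3.9E-28
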