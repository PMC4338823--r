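Package: airliner
Title: Prediction of A-to-I RNA Editing Sites in Non-Repetitive Regions
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for the analysis and prediction of adenosine-to-inosine
    (A-to-I) RNA editing sites outside repetitive elements. Implements a
    logistic-regression scoring model over positional nucleotide probability
    features of sequence windows centered on an adenosine, together with the
    supporting workflow: construction of edited regions from site catalogues
    by a gap-threshold segmentation rule, SNP and repeat filtering,
    positional profile estimation, stratified cross-validation with ROC/AUC
    evaluation, a multiplicative per-neighbor baseline scorer for
    comparison, and motif significance assessment by permutation against
    background sequence pools. A synthetic-data generator produces genomes,
    site catalogues and biased window sets with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    methods,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
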