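#' Load candidate motif records
#'
#' Accepts either a TSV with header columns `id`, `consensus`, `type`,
#' `evalue` (a `width` column, if present, is ignored and recomputed), or a
#' minimal MEME-style text file, from which `MOTIF` lines and the `E =`
#' value of the following `letter-probability matrix` line are parsed.
#' Consensus strings are validated against the IUPAC nucleotide alphabet.
#'
#' @param path Motif file path.
#' @return A data.frame with columns `id`, `consensus`, `width`, `type`
#'   (`"palindromic"` / `"non-palindromic"`) and `evalue`.
#' @export
load_motifs <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  is_meme <- any(grepl("^MEME version|^MOTIF\\b", lines))
  if (is_meme) {
    out <- parse_meme_text(lines)
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE,
                             colClasses = "character")
    need <- c("id", "consensus", "type", "evalue")
    if (!all(need %in% names(tab))) {
      abort(paste0("motif TSV must have columns: ",
                   paste(need, collapse = ", ")), "parse_error")
    }
    out <- data.frame(id = tab$id,
                      consensus = toupper(tab$consensus),
                      type = tolower(tab$type),
                      evalue = as.numeric(tab$evalue),
                      stringsAsFactors = FALSE)
  }
  bad <- grepl(paste0("[^", paste(names(IUPAC_SETS), collapse = ""), "]"),
               out$consensus)
  if (any(bad)) {
    abort(paste0("invalid IUPAC symbol in consensus of motif ",
                 out$id[which(bad)[1]]), "parse_error")
  }
  out$width <- nchar(out$consensus)
  out[, c("id", "consensus", "width", "type", "evalue")]
}

parse_meme_text <- function(lines) {
  motif_idx <- grep("^MOTIF\\b", lines)
  if (length(motif_idx) == 0) abort("no MOTIF blocks found", "parse_error")
  rows <- lapply(motif_idx, function(i) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    consensus <- toupper(tok[2])
    id <- if (length(tok) >= 3) tok[3] else tok[2]
    ev <- NA_real_
    for (j in (i + 1):min(i + 5, length(lines))) {
      m <- regmatches(lines[j],
                      regexpr("E\\s*=\\s*[0-9.eE+-]+", lines[j]))
      if (length(m)) {
        ev <- as.numeric(sub("E\\s*=\\s*", "", m))
        break
      }
    }
    data.frame(id = id, consensus = consensus,
               type = if (identical(consensus, revcomp_iupac(consensus)))
                 "palindromic" else "non-palindromic",
               evalue = ev, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

revcomp_iupac <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Packaged significant-motif table
#'
#' The 13 motifs (4 palindromic, 9 non-palindromic) that survived E-value
#' filtering, ultraconserved-sequence exclusion and the permutation test
#' over edited regions, shipped as a plain-text fixture.
#'
#' @return Motif data.frame as from [load_motifs()].
#' @export
airliner_motifs <- function() {
  load_motifs(system.file("extdata", "table1_motifs.tsv",
                          package = "airliner", mustWork = TRUE))
}

#' Filter motifs on discovery E-value
#'
#' @param motifs Motif data.frame.
#' @param cutoff Keep motifs with `evalue` strictly below this (default
#'   0.05).
#' @return Filtered data.frame.
#' @export
filter_by_evalue <- function(motifs, cutoff = 0.05) {
  if (cutoff <= 0) abort("`cutoff` must be positive", "parameter_error")
  out <- motifs[motifs$evalue < cutoff, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Drop motifs found in ultraconserved background sequences
#'
#' A motif matching anywhere (either strand, IUPAC-compatible, no
#' mismatches) inside a set of ultraconserved sequences -- deeply conserved
#' regions with no known editing -- is considered non-specific and removed.
#'
#' @param motifs Motif data.frame.
#' @param ultraconserved Character vector (or `DNAStringSet`) of A/C/G/T
#'   sequences.
#' @return Motifs with no ultraconserved hit.
#' @export
filter_ultraconserved <- function(motifs, ultraconserved) {
  if (length(ultraconserved) == 0 || nrow(motifs) == 0) return(motifs)
  ultraconserved <- as.character(ultraconserved)
  hit <- vapply(motifs$consensus, function(cons) {
    any(vapply(ultraconserved, function(s) {
      scan_motif(s, cons, both_strands = TRUE) > 0
    }, logical(1)))
  }, logical(1))
  out <- motifs[!hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count IUPAC-compatible motif occurrences in a sequence
#'
#' Counts all (overlapping) positions where the consensus matches, with
#' degenerate IUPAC codes in the motif expanded to their nucleotide sets.
#' Sequence characters outside A/C/G/T (`N`, and soft-masked lowercase
#' runs, which are converted to `N`) match nothing. With
#' `both_strands = TRUE`, occurrences of the reverse-complement consensus
#' are added. A motif wider than the sequence yields zero matches.
#'
#' @param sequence A nucleotide string (vectors are scanned element-wise).
#' @param motif A consensus string or a one-row motif data.frame.
#' @param both_strands Also count reverse-complement matches.
#' @return Integer match count (vector if `sequence` is a vector).
#' @export
scan_motif <- function(sequence, motif, both_strands = TRUE) {
  cons <- if (is.data.frame(motif)) motif$consensus[1] else motif
  cons <- toupper(cons)
  # soft-masked (lowercase) stretches are unmatchable
  seqs <- vapply(sequence, function(s) {
    chartr("acgt", "NNNN", s)
  }, "", USE.NAMES = FALSE)
  w <- nchar(cons)
  subj <- Biostrings::DNAStringSet(seqs)
  count_one <- function(pat) {
    n <- Biostrings::vcountPattern(pat, subj,
                                   fixed = c(pattern = FALSE, subject = TRUE))
    n[nchar(seqs) < w] <- 0L
    n
  }
  out <- count_one(cons)
  if (both_strands) {
    rc <- revcomp_iupac(cons)
    out <- out + count_one(rc)
  }
  as.integer(out)
}

#' Permutation test of motif enrichment against a background pool
#'
#' The observed statistic is, by default, the fraction of the observed
#' sequences containing at least one motif match (presence fraction; a
#' total-match-count statistic is available via `statistic = "count"`).
#' The null distribution is the same statistic on `n_samples` random
#' subsets of `sample_size` sequences drawn without replacement (within
#' each draw) from the background pool. The p-value uses the add-one
#' estimator `p = (1 + #{null >= observed}) / (n_samples + 1)`, which is
#' never exactly zero; significance is declared at p < 0.01.
#'
#' @param motif Consensus string or one-row motif data.frame.
#' @param observed_sequences Character vector of sequences in which the
#'   motif was discovered (e.g. edited-region sequences).
#' @param background_pool Character vector of background sequences (e.g. a
#'   3'-UTR pool), at least `sample_size` long.
#' @param n_samples Number of null draws (>= 1).
#' @param sample_size Sequences per null draw.
#' @param seed Integer seed for the draws.
#' @param statistic `"presence"` or `"count"`.
#' @param both_strands Scan both strands.
#' @return Object of class `"permutation_test"`: list with `p_value`,
#'   `observed`, `null` (length `n_samples`), `significant`, and the
#'   settings.
#' @export
permutation_test <- function(motif, observed_sequences, background_pool,
                             n_samples = 100, sample_size = 1000, seed = 42,
                             statistic = c("presence", "count"),
                             both_strands = TRUE) {
  statistic <- match.arg(statistic)
  if (n_samples < 1) abort("`n_samples` must be >= 1", "parameter_error")
  if (length(background_pool) < sample_size) {
    abort("background pool smaller than `sample_size`", "sampling_error")
  }
  obs_counts <- scan_motif(observed_sequences, motif,
                           both_strands = both_strands)
  pool_counts <- scan_motif(background_pool, motif,
                            both_strands = both_strands)
  stat <- function(counts) {
    if (statistic == "presence") mean(counts > 0) else mean(counts)
  }
  observed <- stat(obs_counts)
  null <- with_seed(seed, {
    vapply(seq_len(n_samples), function(b) {
      stat(pool_counts[sample.int(length(pool_counts), sample_size)])
    }, numeric(1))
  })
  p <- (1 + sum(null >= observed)) / (n_samples + 1)
  structure(list(p_value = p, observed = observed, null = null,
                 significant = p < 0.01, n_samples = n_samples,
                 sample_size = sample_size, statistic = statistic,
                 seed = seed),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf(
    "Permutation test (%s statistic, %d samples of %d): observed %.4f, null mean %.4f, p = %.4g%s\n",
    x$statistic, x$n_samples, x$sample_size, x$observed, mean(x$null),
    x$p_value, if (x$significant) " *" else ""))
  invisible(x)
}
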