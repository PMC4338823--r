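# Internal helpers shared across the package.

NUCS <- c("A", "C", "G", "T")

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# Evaluate `code` under a fixed RNG state without disturbing the caller's
# stream. All randomised entry points funnel through this.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "airliner_error")))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Coerce a genome given as a named character vector or a DNAStringSet to a
# DNAStringSet with contig names stripped to the first whitespace token.
as_genome <- function(genome) {
  if (is.character(genome)) {
    if (is.null(names(genome))) {
      stop("a character genome must be a named vector of contig sequences",
           call. = FALSE)
    }
    genome <- Biostrings::DNAStringSet(genome)
  }
  if (!methods::is(genome, "DNAStringSet")) {
    stop("`genome` must be a DNAStringSet or a named character vector",
         call. = FALSE)
  }
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

validate_sites <- function(sites) {
  if (!is.data.frame(sites) ||
      !all(c("chrom", "pos", "strand") %in% names(sites))) {
    stop("`sites` must be a data.frame with columns chrom, pos, strand",
         call. = FALSE)
  }
  if (nrow(sites) > 0) {
    if (any(sites$pos < 0)) stop("site positions must be >= 0", call. = FALSE)
    if (!all(sites$strand %in% c("+", "-"))) {
      stop("site strand must be '+' or '-'", call. = FALSE)
    }
  }
  invisible(sites)
}

# Validates a set of A-centered windows and returns the common radius.
validate_windows <- function(windows, what = "windows") {
  if (length(windows) == 0) {
    abort(paste0(what, " is empty"), "empty_training_error")
  }
  len <- unique(nchar(windows))
  if (length(len) != 1L) {
    abort(paste0(what, " have mixed lengths: ",
                 paste(sort(len), collapse = ", ")), "shape_error")
  }
  if (len %% 2L == 0L) {
    abort(paste0(what, " must have odd length (2*radius + 1)"), "shape_error")
  }
  radius <- (len - 1L) %/% 2L
  if (any(grepl("[^ACGT]", windows))) {
    abort(paste0(what, " contain characters outside A/C/G/T"),
          "ambiguity_error")
  }
  centers <- substr(windows, radius + 1L, radius + 1L)
  if (any(centers != "A")) {
    abort(paste0(what, " must be centered on an adenosine"),
          "center_base_error")
  }
  radius
}
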