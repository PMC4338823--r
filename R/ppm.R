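#' Positional nucleotide probability matrix from A-centered windows
#'
#' Estimates, for every window position i, the probability of observing each
#' nucleotide j -- P(j, i) when fitted on edited windows, P'(j, i) on
#' un-edited ones. Counts are Laplace-smoothed:
#' `probs[j, i] = (count[j, i] + alpha) / (n + 4 * alpha)`. The default
#' `alpha = 1` keeps every probability strictly inside (0, 1), so no window
#' can later receive an infinite logit; `alpha = 0` gives the raw maximum
#' likelihood estimate.
#'
#' @param windows Character vector of uppercase A-centered windows, all of
#'   the same odd length.
#' @param pseudocount Smoothing constant alpha >= 0.
#' @return A 4 x (2 * radius + 1) matrix of class `"ppm"` with rows A, C, G,
#'   T, and attributes `radius`, `n` (training count) and `pseudocount`.
#'   Every column sums to one.
#' @examples
#' build_profile(c("CAAAG", "TTACG", "GCAGA"), pseudocount = 1)
#' @export
build_profile <- function(windows, pseudocount = 1) {
  radius <- validate_windows(windows)
  if (pseudocount < 0) abort("`pseudocount` must be >= 0", "parameter_error")
  L <- 2L * radius + 1L
  n <- length(windows)
  chars <- matrix(unlist(strsplit(windows, ""), use.names = FALSE),
                  nrow = n, ncol = L, byrow = TRUE)
  counts <- vapply(seq_len(L), function(i) {
    tabulate(match(chars[, i], NUCS), nbins = 4L)
  }, numeric(4))
  probs <- (counts + pseudocount) / (n + 4 * pseudocount)
  dimnames(probs) <- list(NUCS, NULL)
  structure(probs, class = "ppm", radius = radius, n = n,
            pseudocount = pseudocount)
}

#' @export
print.ppm <- function(x, digits = 3, ...) {
  r <- attr(x, "radius")
  cat("Positional probability matrix: radius", r, "(",
      2 * r + 1, "positions ), n =", attr(x, "n"),
      ", pseudocount =", attr(x, "pseudocount"), "\n")
  m <- unclass(x)
  attributes(m)[c("radius", "n", "pseudocount")] <- NULL
  colnames(m) <- as.character(seq_len(ncol(m)) - r - 1L)
  print(round(m, digits))
  invisible(x)
}

ppm_radius <- function(ppm) attr(ppm, "radius")

#' Positional-probability features for sequence windows
#'
#' Maps each window s to the feature vector
#' `(P(s[1], 1), ..., P(s[L], L), P'(s[1], 1), ..., P'(s[L], L))` with
#' `L = 2 * radius + 1`: per-position table lookups into the edited and
#' un-edited profiles, no normalization. These are the covariates of the
#' logistic scoring model.
#'
#' @param windows Character vector of A-centered windows.
#' @param ppm_edited,ppm_unedited `"ppm"` matrices of matching radius.
#' @return A numeric matrix with one row per window and `2 * L` columns
#'   (`P_1..P_L`, then `Pp_1..Pp_L`); a single window still yields a
#'   one-row matrix.
#' @export
featurize <- function(windows, ppm_edited, ppm_unedited) {
  radius <- validate_windows(windows)
  if (ppm_radius(ppm_edited) != radius || ppm_radius(ppm_unedited) != radius) {
    abort("window radius does not match profile radius", "shape_error")
  }
  L <- 2L * radius + 1L
  n <- length(windows)
  chars <- matrix(match(unlist(strsplit(windows, ""), use.names = FALSE),
                        NUCS),
                  nrow = n, ncol = L, byrow = TRUE)
  pos <- matrix(rep(seq_len(L), each = n), nrow = n)
  f1 <- matrix(unclass(ppm_edited)[cbind(as.vector(chars), as.vector(pos))],
               nrow = n)
  f2 <- matrix(unclass(ppm_unedited)[cbind(as.vector(chars), as.vector(pos))],
               nrow = n)
  out <- cbind(f1, f2)
  colnames(out) <- c(paste0("P_", seq_len(L)), paste0("Pp_", seq_len(L)))
  out
}

#' Write / read a positional profile
#'
#' The on-disk form is a TSV with one row per window position and four
#' probability columns, preceded by a single `#`-prefixed JSON header line
#' carrying `radius`, `pseudocount` and `n`.
#'
#' @param ppm A `"ppm"` matrix.
#' @param path File path.
#' @return `write_profile` returns `path` invisibly; `read_profile` returns
#'   the reconstructed `"ppm"`.
#' @export
write_profile <- function(ppm, path) {
  hdr <- jsonlite::toJSON(list(radius = attr(ppm, "radius"),
                               pseudocount = attr(ppm, "pseudocount"),
                               n = attr(ppm, "n")), auto_unbox = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", hdr), con)
  writeLines(paste(c("position", NUCS), collapse = "\t"), con)
  m <- unclass(ppm)
  for (i in seq_len(ncol(m))) {
    writeLines(paste(c(i, format(m[, i], digits = 17)), collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  meta <- jsonlite::fromJSON(sub("^#", "", lines[1]))
  tab <- utils::read.table(text = lines[-1], header = TRUE, sep = "\t")
  probs <- t(as.matrix(tab[, NUCS]))
  dimnames(probs) <- list(NUCS, NULL)
  structure(probs, class = "ppm", radius = meta$radius, n = meta$n,
            pseudocount = meta$pseudocount)
}
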