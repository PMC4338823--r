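#' Multiplicative per-neighbor baseline scorer
#'
#' A structural reimplementation of the multiplicative family of editing
#' predictors: the percent editing score of a window is a base rate times
#' one positive multiplier per configured neighbor offset, chosen by the
#' nucleotide observed at that offset. Offsets are relative to the central
#' adenosine and exclude 0 (the edited base itself). A window is called
#' edited when its score exceeds `threshold_percent`; the conventional
#' cutoff is 9.6 percent. Coefficient tables are user-supplied, e.g. one
#' table per deaminase.
#'
#' @param coefficients A data.frame with columns `offset` (integer, non
#'   zero), `nucleotide` (A/C/G/T) and `multiplier` (> 0), or a named list
#'   of per-offset named multiplier vectors.
#' @param base_rate Percent scale factor multiplying the product.
#' @param threshold_percent Decision cutoff on the percent score.
#' @param id Optional label (e.g. `"ADAR1"`).
#' @return An object of class `"multiplicative_scorer"`.
#' @examples
#' tab <- data.frame(offset = c(-1, -1, -1, -1, 1, 1, 1, 1),
#'                   nucleotide = rep(c("A", "C", "G", "T"), 2),
#'                   multiplier = c(1, 1, 1, 2, 1, 1, 3, 1))
#' sc <- multiplicative_scorer(tab, base_rate = 5)
#' multiplicative_score(sc, "TAG")  # 5 * 2 * 3 = 30
#' @export
multiplicative_scorer <- function(coefficients, base_rate = 100,
                                  threshold_percent = 9.6, id = NULL) {
  if (is.data.frame(coefficients)) {
    stopifnot(all(c("offset", "nucleotide", "multiplier") %in%
                    names(coefficients)))
    tabs <- lapply(split(coefficients, coefficients$offset), function(d) {
      stats::setNames(d$multiplier, d$nucleotide)
    })
  } else {
    tabs <- coefficients
  }
  offsets <- as.integer(names(tabs))
  if (any(offsets == 0L)) {
    abort("offset 0 (the edited adenosine) cannot carry a multiplier",
          "configuration_error")
  }
  for (o in names(tabs)) {
    v <- tabs[[o]]
    if (any(!is.finite(v)) || any(v <= 0)) {
      abort(paste0("non-positive multiplier at offset ", o),
            "configuration_error")
    }
    if (!all(names(v) %in% NUCS)) {
      abort(paste0("invalid nucleotide in table at offset ", o),
            "configuration_error")
    }
  }
  structure(list(tables = tabs, offsets = offsets, base_rate = base_rate,
                 threshold_percent = threshold_percent, id = id),
            class = "multiplicative_scorer")
}

#' Load a multiplicative coefficient table from TSV
#'
#' Expected columns: `offset`, `nucleotide`, `multiplier` (tab-separated,
#' with header).
#'
#' @param path TSV path.
#' @inheritParams multiplicative_scorer
#' @return A `"multiplicative_scorer"`.
#' @export
read_scorer <- function(path, base_rate = 100, threshold_percent = 9.6,
                        id = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  multiplicative_scorer(tab, base_rate = base_rate,
                        threshold_percent = threshold_percent, id = id)
}

#' Score windows with a multiplicative scorer
#'
#' @param scorer A `"multiplicative_scorer"`.
#' @param windows Character vector of A-centered windows; every configured
#'   offset must fall inside the window.
#' @return Numeric vector of percent scores.
#' @export
multiplicative_score <- function(scorer, windows) {
  radius <- validate_windows(windows)
  if (any(abs(scorer$offsets) > radius)) {
    abort("scorer offsets exceed the window radius", "configuration_error")
  }
  score <- rep(scorer$base_rate, length(windows))
  for (o in scorer$offsets) {
    nt <- substr(windows, radius + 1L + o, radius + 1L + o)
    mult <- scorer$tables[[as.character(o)]][nt]
    if (anyNA(mult)) {
      abort(sprintf("no multiplier for nucleotide '%s' at offset %d",
                    nt[which(is.na(mult))[1]], o), "configuration_error")
    }
    score <- score * unname(mult)
  }
  score
}

#' @export
print.multiplicative_scorer <- function(x, ...) {
  cat("Multiplicative editing scorer",
      if (!is.null(x$id)) paste0("[", x$id, "]"), "\n")
  cat("  offsets:", paste(sort(x$offsets), collapse = ", "),
      "| base rate:", x$base_rate,
      "| threshold:", x$threshold_percent, "%\n")
  invisible(x)
}

#' @export
predict.multiplicative_scorer <- function(object, newdata,
                                          type = c("score", "class"), ...) {
  type <- match.arg(type)
  s <- multiplicative_score(object, newdata)
  if (type == "score") s
  else ifelse(s > object$threshold_percent, "edited", "unedited")
}
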