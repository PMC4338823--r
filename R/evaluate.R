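#' ROC curve and area by tie-grouped thresholding
#'
#' Sweeps all distinct score values as thresholds, grouping tied scores
#' into a single step so the curve is deterministic, and accumulates
#' true- and false-positive rates from (0, 0) to (1, 1). The area is the
#' trapezoid-rule integral, which for this construction equals the
#' Mann-Whitney concordance probability with half credit for ties.
#'
#' @param scores Numeric scores (larger = more edited-like).
#' @param labels Logical, 0/1 or `"edited"`-vs-other labels marking the
#'   positive class.
#' @return Object of class `"airliner_roc"`: list with `thresholds`,
#'   `tpr`, `fpr` (parallel vectors, leading (0, 0) point included) and
#'   `auc`.
#' @export
roc_auc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  if (length(scores) != length(y)) {
    stop("`scores` and `labels` differ in length", call. = FALSE)
  }
  n_pos <- sum(y == 1)
  n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0) {
    abort("AUC is undefined: only one class present", "undefined_auc_error")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  yy <- y[ord]
  # one step per distinct score value
  last <- cumsum(rle(s)$lengths)
  tp <- cumsum(yy)[last]
  fp <- cumsum(1 - yy)[last]
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = c(Inf, s[last]), tpr = tpr, fpr = fpr,
                 auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "airliner_roc")
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) {
    stopifnot(all(labels %in% c(0, 1)))
    return(as.integer(labels))
  }
  as.integer(labels %in% c("edited", "editing", "pos", "positive", "1"))
}

#' @export
print.airliner_roc <- function(x, ...) {
  cat(sprintf("ROC over %d positives / %d negatives: AUC = %.4f (%d steps)\n",
              x$n_pos, x$n_neg, x$auc, length(x$thresholds) - 1L))
  invisible(x)
}

#' @export
plot.airliner_roc <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "l", xlab = "False positive rate",
                 ylab = "True positive rate",
                 main = sprintf("ROC (AUC = %.4f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}

#' Row-percent confusion matrix
#'
#' Cross-tabulates actual classes (edited vs random) against predicted
#' calls (edited vs unedited) and reports each row as percentages of its
#' actual-class total -- the presentation conventional for editing-predictor
#' comparisons.
#'
#' @param calls Predicted labels (`"edited"` / `"unedited"`, or logical
#'   with `TRUE` = edited).
#' @param truth Actual labels (`"edited"` / `"random"`, or logical with
#'   `TRUE` = edited).
#' @return Object of class `"confusion_pct"` with `$percent` and `$counts`
#'   2 x 2 matrices (rows: actual edited / random; columns: predicted
#'   edited / unedited).
#' @export
confusion_matrix_pct <- function(calls, truth) {
  if (length(calls) != length(truth)) {
    stop("`calls` and `truth` differ in length", call. = FALSE)
  }
  if (length(calls) == 0) {
    abort("cannot tabulate an empty evaluation", "empty_evaluation_error")
  }
  pred_pos <- if (is.logical(calls)) calls else calls == "edited"
  act_pos <- if (is.logical(truth)) truth else
    truth %in% c("edited", "editing")
  counts <- rbind(
    edited = c(sum(act_pos & pred_pos), sum(act_pos & !pred_pos)),
    random = c(sum(!act_pos & pred_pos), sum(!act_pos & !pred_pos)))
  colnames(counts) <- c("edited", "unedited")
  pct <- counts
  totals <- rowSums(counts)
  for (i in 1:2) {
    pct[i, ] <- if (totals[i] > 0) 100 * counts[i, ] / totals[i] else NA_real_
  }
  structure(list(percent = pct, counts = counts), class = "confusion_pct")
}

#' @export
print.confusion_pct <- function(x, digits = 2, ...) {
  cat("Confusion matrix (row percentages; rows = actual, cols = predicted)\n")
  print(round(x$percent, digits))
  invisible(x)
}

#' Stratified k-fold cross-validation of the editing model
#'
#' Builds near-equal stratified folds from a seeded shuffle of each class,
#' then, for each fold, estimates the positional profiles and fits the
#' logistic model on the remaining folds only -- held-out windows never
#' contribute to the profiles they are scored against -- and scores the
#' held-out fold. Reports the per-fold misclassification error at the 0.5
#' threshold, the mean error, per-fold AUCs with their mean, and the
#' pooled out-of-fold score table with its single pooled ROC.
#'
#' @param pos,neg Positive (edited) and negative window sets.
#' @param k Fold count (>= 2).
#' @param seed Integer seed for the fold shuffle.
#' @param threshold Classification cutoff for the error rate.
#' @param profile_scope `"fold"` (default; profiles from training folds
#'   only) or `"all"` (the naive leaky variant that estimates profiles
#'   from the full dataset, kept for comparison).
#' @inheritParams airliner
#' @return Object of class `"airliner_cv"`: list with `per_fold` (fold, n,
#'   error, auc), `mean_error`, `auc_pooled`, `auc_mean_folds`, `roc`
#'   (pooled [roc_auc()] object), `scores` (score, label, fold for every
#'   window, out-of-fold), `k`, `seed`.
#' @export
kfold_cross_validate <- function(pos, neg, k = 10, seed = 42,
                                 pseudocount = 1, lambda = 1e-3,
                                 threshold = 0.5,
                                 profile_scope = c("fold", "all")) {
  profile_scope <- match.arg(profile_scope)
  r <- validate_windows(pos)
  stopifnot(validate_windows(neg) == r)
  if (k < 2) abort("`k` must be at least 2", "parameter_error")
  if (k > length(pos) || k > length(neg)) {
    abort("more folds than windows in a class", "stratification_error")
  }
  fold_pos <- with_seed(seed, sample(rep_len(seq_len(k), length(pos))))
  fold_neg <- with_seed(seed + 1L, sample(rep_len(seq_len(k), length(neg))))
  all_ppms <- if (profile_scope == "all") {
    list(edited = build_profile(pos, pseudocount),
         unedited = build_profile(neg, pseudocount))
  } else NULL
  per_fold <- vector("list", k)
  scores <- vector("list", k)
  for (f in seq_len(k)) {
    tr_pos <- pos[fold_pos != f]
    tr_neg <- neg[fold_neg != f]
    te_pos <- pos[fold_pos == f]
    te_neg <- neg[fold_neg == f]
    if (length(tr_pos) == 0 || length(tr_neg) == 0) {
      abort("a class is absent from a training split", "stratification_error")
    }
    fit <- airliner(tr_pos, tr_neg, pseudocount = pseudocount,
                    lambda = lambda, ppms = all_ppms)
    te <- c(te_pos, te_neg)
    y <- rep(c(1, 0), c(length(te_pos), length(te_neg)))
    p <- if (length(te)) predict(fit, te) else numeric(0)
    err <- if (length(te)) mean((p > threshold) != (y == 1)) else NA_real_
    auc_f <- if (length(te_pos) && length(te_neg)) {
      roc_auc(p, y)$auc
    } else NA_real_
    per_fold[[f]] <- data.frame(fold = f, n = length(te), error = err,
                                auc = auc_f)
    scores[[f]] <- data.frame(score = p, label = y, fold = rep(f, length(te)))
  }
  per_fold <- do.call(rbind, per_fold)
  scores <- do.call(rbind, scores)
  pooled <- roc_auc(scores$score, scores$label)
  structure(list(per_fold = per_fold,
                 mean_error = mean(per_fold$error, na.rm = TRUE),
                 auc_pooled = pooled$auc,
                 auc_mean_folds = mean(per_fold$auc, na.rm = TRUE),
                 roc = pooled, scores = scores,
                 fold_pos = fold_pos, fold_neg = fold_neg,
                 k = k, seed = seed, threshold = threshold,
                 profile_scope = profile_scope),
            class = "airliner_cv")
}

#' @export
print.airliner_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (seed %d, profiles from %s data)\n",
              x$k, x$seed,
              if (x$profile_scope == "fold") "training-fold" else "all"))
  cat(sprintf("  mean error at %.2f: %.4f\n", x$threshold, x$mean_error))
  cat(sprintf("  AUC: pooled %.4f, mean over folds %.4f\n",
              x$auc_pooled, x$auc_mean_folds))
  invisible(x)
}

#' Compare the logistic model against a multiplicative baseline
#'
#' Scores every window with the fitted logistic model and with one or more
#' multiplicative coefficient tables, then reports paired ROC/AUC results
#' and confusion matrices (the logistic model thresholded at
#' `threshold`, the baseline at its percent cutoff). When the baseline
#' provides several tables (e.g. one per deaminase) and the dataset does
#' not record which enzyme produced each site,
#' `selection = "max_for_pos_min_for_neg"` applies the fairness protocol:
#' a truly edited window receives its maximum score over tables, a random
#' window its minimum, so the baseline is always judged on its most
#' favorable table.
#'
#' @param pos,neg Edited and random window sets.
#' @param model Fitted `"airliner"` model.
#' @param scorers A `"multiplicative_scorer"` or list of them.
#' @param selection `"single"` (one table required) or
#'   `"max_for_pos_min_for_neg"` (>= 2 tables required).
#' @param threshold Probability cutoff for the logistic model's calls.
#' @return Object of class `"scorer_comparison"`: list with `primary` and
#'   `secondary`, each holding `roc` and `confusion`, plus the per-window
#'   `scores` data.frame.
#' @export
compare_scorers <- function(pos, neg, model, scorers,
                            selection = c("single",
                                          "max_for_pos_min_for_neg"),
                            threshold = 0.5) {
  selection <- match.arg(selection)
  if (inherits(scorers, "multiplicative_scorer")) scorers <- list(scorers)
  if (selection == "max_for_pos_min_for_neg" && length(scorers) < 2) {
    abort("max/min selection needs at least two coefficient tables",
          "configuration_error")
  }
  if (selection == "single" && length(scorers) != 1) {
    abort("selection = 'single' expects exactly one coefficient table",
          "configuration_error")
  }
  windows <- c(pos, neg)
  y <- rep(c(1, 0), c(length(pos), length(neg)))
  p_primary <- predict(model, windows)
  sec_mat <- vapply(scorers, multiplicative_score, numeric(length(windows)),
                    windows = windows)
  sec_mat <- matrix(sec_mat, nrow = length(windows))
  s_secondary <- if (selection == "single") {
    sec_mat[, 1]
  } else {
    ifelse(y == 1, apply(sec_mat, 1, max), apply(sec_mat, 1, min))
  }
  cutoff <- scorers[[1]]$threshold_percent
  truth <- ifelse(y == 1, "edited", "random")
  structure(list(
    primary = list(
      roc = roc_auc(p_primary, y),
      confusion = confusion_matrix_pct(
        ifelse(p_primary > threshold, "edited", "unedited"), truth)),
    secondary = list(
      roc = roc_auc(s_secondary, y),
      confusion = confusion_matrix_pct(
        ifelse(s_secondary > cutoff, "edited", "unedited"), truth)),
    scores = data.frame(primary = p_primary, secondary = s_secondary,
                        label = y),
    selection = selection, threshold = threshold,
    secondary_threshold = cutoff
  ), class = "scorer_comparison")
}

#' @export
print.scorer_comparison <- function(x, ...) {
  cat("Scorer comparison (", nrow(x$scores), " windows, selection = ",
      x$selection, ")\n", sep = "")
  cat(sprintf("  logistic model: AUC %.4f (cutoff %.2f)\n",
              x$primary$roc$auc, x$threshold))
  print(x$primary$confusion)
  cat(sprintf("  multiplicative baseline: AUC %.4f (cutoff %.1f%%)\n",
              x$secondary$roc$auc, x$secondary_threshold))
  print(x$secondary$confusion)
  invisible(x)
}
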