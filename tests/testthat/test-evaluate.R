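test_that("ROC/AUC matches the concordance-pair oracle", {
  r <- roc_auc(c(0.9, 0.8, 0.3), c(1, 0, 1))
  expect_equal(r$auc, 0.5)  # one concordant, one discordant pos x neg pair

  perfect <- roc_auc(c(5, 4, 1, 0), c(1, 1, 0, 0))
  expect_equal(perfect$auc, 1.0)

  set.seed(77)
  for (rep in 1:50) {
    n <- sample(4:60, 1)
    # coarse scores force ties within and across classes
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    expect_equal(roc_auc(scores, labels)$auc, oracle_auc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("ROC curves are monotone and internally consistent", {
  set.seed(3)
  scores <- round(rnorm(300), 1)
  labels <- rbinom(300, 1, 0.4)
  r <- roc_auc(scores, labels)
  expect_true(all(diff(r$tpr) >= 0))
  expect_true(all(diff(r$fpr) >= 0))
  expect_equal(r$tpr[1], 0)
  expect_equal(r$fpr[1], 0)
  expect_equal(r$tpr[length(r$tpr)], 1)
  expect_equal(r$fpr[length(r$fpr)], 1)
  trap <- sum(diff(r$fpr) * (head(r$tpr, -1) + tail(r$tpr, -1)) / 2)
  expect_equal(r$auc, trap, tolerance = 1e-9)
  expect_error(roc_auc(1:3, c(1, 1, 1)), class = "undefined_auc_error")
})

test_that("AUC of label-independent scores is near one half", {
  set.seed(99)
  scores <- runif(10000)
  labels <- rbinom(10000, 1, 0.5)
  a <- roc_auc(scores, labels)$auc
  expect_gte(a, 0.48)
  expect_lte(a, 0.52)
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(12)
  scores <- round(rnorm(150), 1)
  labels <- rbinom(150, 1, 0.5)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(scores, labels)$auc, ref, tolerance = 1e-12)
})

test_that("confusion matrices report row percentages of actual classes", {
  cm <- confusion_matrix_pct(c("edited", "unedited", "edited", "unedited"),
                             c("edited", "edited", "random", "random"))
  expect_equal(unname(cm$percent), matrix(c(50, 50, 50, 50), 2))

  all_right <- confusion_matrix_pct(c("edited", "unedited"),
                                    c("edited", "random"))
  expect_equal(unname(all_right$percent), matrix(c(100, 0, 0, 100), 2))

  expect_error(confusion_matrix_pct(character(), character()),
               class = "empty_evaluation_error")

  set.seed(4)
  calls <- sample(c("edited", "unedited"), 1000, replace = TRUE)
  truth <- sample(c("edited", "random"), 1000, replace = TRUE)
  cm2 <- confusion_matrix_pct(calls, truth)
  expect_equal(rowSums(cm2$percent), c(edited = 100, random = 100),
               tolerance = 1e-6)
  # brute-force tally
  expect_equal(cm2$counts["edited", "edited"],
               sum(truth == "edited" & calls == "edited"))
  expect_equal(cm2$counts["random", "unedited"],
               sum(truth == "random" & calls == "unedited"))
  expect_equal(sum(cm2$counts), 1000)
})

test_that("cross-validation folds partition the data and are reproducible", {
  w <- generate_window_sets(bias_spec(radius = 3, n_pos = 40, n_neg = 40,
                                      seed = 10))
  cv1 <- kfold_cross_validate(w$pos, w$neg, k = 5, seed = 7)
  cv2 <- kfold_cross_validate(w$pos, w$neg, k = 5, seed = 7)
  expect_identical(cv1$fold_pos, cv2$fold_pos)
  expect_identical(cv1$scores, cv2$scores)
  # every window lands in exactly one test fold
  expect_equal(sort(as.vector(table(cv1$fold_pos))), rep(8L, 5))
  expect_equal(nrow(cv1$scores), 80)
  expect_equal(sum(cv1$per_fold$n), 80)

  # leave-one-out within a class: 10 singleton positive folds
  loo <- kfold_cross_validate(w$pos[1:10], w$neg[1:10], k = 10, seed = 1)
  expect_equal(as.vector(table(loo$fold_pos)), rep(1L, 10))

  expect_error(kfold_cross_validate(w$pos[1:3], w$neg, k = 5, seed = 1),
               class = "stratification_error")
  expect_error(kfold_cross_validate(w$pos, w$neg, k = 1, seed = 1),
               class = "parameter_error")
})

test_that("separable classes cross-validate nearly perfectly", {
  r <- 3
  sep <- matrix(0, 4, 7, dimnames = list(c("A", "C", "G", "T"), NULL))
  sep["T", ] <- 1
  sep[, 4] <- c(1, 0, 0, 0)
  unsep <- matrix(0, 4, 7, dimnames = list(c("A", "C", "G", "T"), NULL))
  unsep["C", ] <- 1                          # flanks all C instead of all T
  unsep[, 4] <- c(1, 0, 0, 0)
  w <- generate_window_sets(bias_spec(radius = r, edited_profile = sep,
                                      unedited_profile = unsep,
                                      n_pos = 60, n_neg = 60, seed = 2))
  cv <- kfold_cross_validate(w$pos, w$neg, k = 5, seed = 3)
  expect_lte(cv$mean_error, 0.05)
  expect_equal(cv$auc_pooled, 1.0)
})

test_that("held-out windows never shape the profiles they are scored with", {
  w <- generate_window_sets(bias_spec(radius = 3, n_pos = 60, n_neg = 60,
                                      seed = 20))
  clean <- kfold_cross_validate(w$pos, w$neg, k = 4, seed = 5)
  leaky <- kfold_cross_validate(w$pos, w$neg, k = 4, seed = 5,
                                profile_scope = "all")
  # same folds, different profile scope: the scores must differ
  expect_identical(clean$fold_pos, leaky$fold_pos)
  expect_false(isTRUE(all.equal(clean$scores$score, leaky$scores$score)))
})

test_that("the comparison protocol applies max/min table selection", {
  w <- generate_window_sets(bias_spec(radius = 2, n_pos = 40, n_neg = 40,
                                      seed = 6))
  fit <- airliner(w$pos, w$neg)
  full_grid <- expand.grid(offset = c(-2L, -1L, 1L, 2L),
                           nucleotide = c("A", "C", "G", "T"),
                           stringsAsFactors = FALSE)
  set.seed(9)
  tabA <- transform(full_grid, multiplier = runif(nrow(full_grid), 0.2, 1))
  tabB <- transform(full_grid, multiplier = runif(nrow(full_grid), 1, 4))
  scA <- multiplicative_scorer(tabA, base_rate = 10)
  scB <- multiplicative_scorer(tabB, base_rate = 10)

  # identical tables: selection cannot change anything
  same <- compare_scorers(w$pos, w$neg, fit, list(scA, scA),
                          selection = "max_for_pos_min_for_neg")
  single <- compare_scorers(w$pos, w$neg, fit, scA)
  expect_equal(same$scores$secondary, single$scores$secondary)

  # tables ordered A < B everywhere: edited get B's score, random get A's
  two <- compare_scorers(w$pos, w$neg, fit, list(scA, scB),
                         selection = "max_for_pos_min_for_neg")
  sA <- multiplicative_score(scA, c(w$pos, w$neg))
  sB <- multiplicative_score(scB, c(w$pos, w$neg))
  y <- rep(c(1, 0), each = 40)
  expect_equal(two$scores$secondary, ifelse(y == 1, pmax(sA, sB),
                                            pmin(sA, sB)))
  expect_equal(two$scores$secondary[1:40], sB[1:40])
  expect_equal(two$scores$secondary[41:80], sA[41:80])

  expect_error(compare_scorers(w$pos, w$neg, fit, scA,
                               selection = "max_for_pos_min_for_neg"),
               class = "configuration_error")
  expect_error(compare_scorers(w$pos, w$neg, fit, list(scA, scB),
                               selection = "single"),
               class = "configuration_error")
})
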