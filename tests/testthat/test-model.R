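test_that("intercept-only fits recover the closed-form logit prevalence", {
  # degenerate all-zero design: the optimum is beta0 = logit(mean(y))
  X <- matrix(0, 40, 3)
  y <- rep(c(1, 0), each = 20)
  fit <- ridge_logistic(X, y, lambda = 1e-3)
  expect_equal(fit$beta0, 0, tolerance = 1e-8)
  expect_equal(fit$beta, rep(0, 3), tolerance = 1e-8)

  y2 <- rep(c(1, 0), c(10, 30))
  fit2 <- ridge_logistic(X, y2, lambda = 1e-3)
  expect_equal(fit2$beta0, qlogis(0.25), tolerance = 1e-8)
})

test_that("the Newton fit matches a generic numerical minimizer", {
  set.seed(14)
  for (rep in 1:20) {
    n <- sample(20:60, 1)
    p <- sample(1:6, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- rbinom(n, 1, plogis(X %*% rnorm(p)))
    if (length(unique(y)) < 2) next
    lambda <- sample(c(1e-3, 1e-2, 0.1, 1), 1)
    fit <- ridge_logistic(X, y, lambda = lambda)
    ref <- oracle_ridge_logistic(X, y, lambda)
    expect_equal(c(fit$beta0, fit$beta), unname(ref), tolerance = 1e-4)
  }
})

test_that("the penalized-likelihood gradient vanishes at the solution", {
  w <- generate_window_sets(bias_spec(radius = 3, n_pos = 120, n_neg = 120,
                                      seed = 21))
  fit <- airliner(w$pos, w$neg)
  expect_lte(fit$fit_info$gradient_norm, 1e-8)
  # central finite differences of the objective around the solution
  feats <- featurize(c(w$pos, w$neg), fit$ppm_edited, fit$ppm_unedited)
  L <- 7
  X <- cbind(feats[, 1:L], -feats[, L + 1:L])
  y <- rep(c(1, 0), each = 120)
  th <- c(fit$beta0, fit$beta, fit$beta_prime)
  pen <- c(0, rep(fit$lambda, 2 * L))
  obj <- function(t) {
    eta <- drop(cbind(1, X) %*% t)
    sum(ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta)))) -
      sum(y * eta) + sum(pen * t^2) / 2
  }
  h <- 1e-6
  num_grad <- vapply(seq_along(th), function(j) {
    e <- numeric(length(th)); e[j] <- h
    (obj(th + e) - obj(th - e)) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(num_grad)), 1e-6)
})

test_that("fits are deterministic and ridge shrinks the coefficients", {
  w <- generate_window_sets(bias_spec(radius = 4, n_pos = 150, n_neg = 150,
                                      seed = 5))
  f1 <- airliner(w$pos, w$neg)
  f2 <- airliner(w$pos, w$neg)
  expect_identical(coef(f1), coef(f2))

  norms <- vapply(c(1e-4, 1e-2, 1, 100), function(l) {
    f <- airliner(w$pos, w$neg, lambda = l)
    sqrt(sum(c(f$beta, f$beta_prime)^2))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-8))
})

test_that("prediction applies the logistic link to the linear predictor", {
  w <- generate_window_sets(bias_spec(radius = 2, n_pos = 30, n_neg = 30,
                                      seed = 2))
  fit <- airliner(w$pos, w$neg)
  # zeroed-out model scores 0.5 everywhere; huge intercept saturates
  fit0 <- fit
  fit0$beta0 <- 0
  fit0$beta[] <- 0
  fit0$beta_prime[] <- 0
  expect_equal(unname(predict(fit0, w$pos[1:5])), rep(0.5, 5))
  fit0$beta0 <- 30
  expect_true(all(predict(fit0, w$pos[1:5]) > 1 - 1e-9))

  # hand-computed sigma(beta0 + sum beta P - sum beta' P') on a 3-nt model
  fit3 <- airliner(c("CAG", "TAG", "AAG"), c("GAC", "CAC", "TAT"),
                   pseudocount = 1, lambda = 0.05)
  win <- "GAT"
  fe <- drop(featurize(win, fit3$ppm_edited, fit3$ppm_unedited))
  eta <- fit3$beta0 + sum(fit3$beta * fe[1:3]) - sum(fit3$beta_prime * fe[4:6])
  expect_equal(unname(predict(fit3, win)), plogis(eta), tolerance = 1e-12)
  expect_equal(unname(predict(fit3, win, type = "link")), eta,
               tolerance = 1e-12)

  expect_error(predict(fit3, "AAAAA"), class = "shape_error")
})

test_that("classification is strict at the threshold", {
  w <- generate_window_sets(bias_spec(radius = 2, n_pos = 30, n_neg = 30,
                                      seed = 2))
  fit <- airliner(w$pos, w$neg)
  fit$beta0 <- 0
  fit$beta[] <- 0
  fit$beta_prime[] <- 0
  # probability is exactly 0.5 -> called unedited under the > 0.5 rule
  expect_equal(unique(classify(fit, w$pos)), "unedited")
  fit$beta0 <- qlogis(0.51)
  expect_equal(unique(classify(fit, w$pos)), "edited")
  expect_equal(unique(classify(fit, w$pos, threshold = 0.9)), "unedited")
  expect_error(classify(fit, w$pos, threshold = 1), class = "parameter_error")
})

test_that("strong positional bias is learned, absent bias is not", {
  # disjoint flank supports: flanks all-T for edited, all-C for un-edited
  r <- 3
  sep <- matrix(0, 4, 2 * r + 1, dimnames = list(c("A", "C", "G", "T"), NULL))
  sep["T", ] <- 1
  sep[, r + 1] <- c(1, 0, 0, 0)
  unsep <- matrix(0, 4, 2 * r + 1, dimnames = list(c("A", "C", "G", "T"), NULL))
  unsep["C", ] <- 1
  unsep[, r + 1] <- c(1, 0, 0, 0)
  w <- generate_window_sets(bias_spec(radius = r, edited_profile = sep,
                                      unedited_profile = unsep,
                                      n_pos = 100, n_neg = 100, seed = 8))
  fit <- airliner(w$pos, w$neg)
  acc <- mean(classify(fit, c(w$pos, w$neg)) ==
                rep(c("edited", "unedited"), each = 100))
  expect_gte(acc, 0.95)

  # identical generating profiles: training accuracy hovers at chance
  spec0 <- bias_spec(radius = 3, edited_profile = uniform_profile(3),
                     unedited_profile = uniform_profile(3),
                     n_pos = 1000, n_neg = 1000, seed = 42)
  w0 <- generate_window_sets(spec0)
  fit0 <- airliner(w0$pos, w0$neg)
  acc0 <- mean(classify(fit0, c(w0$pos, w0$neg)) ==
                 rep(c("edited", "unedited"), each = 1000))
  expect_gte(acc0, 0.45)
  expect_lte(acc0, 0.55)
})

test_that("models survive JSON serialization", {
  w <- generate_window_sets(bias_spec(radius = 3, n_pos = 40, n_neg = 40,
                                      seed = 12))
  fit <- airliner(w$pos, w$neg)
  f <- withr::local_tempfile(fileext = ".json")
  write_airliner(fit, f)
  back <- read_airliner(f)
  expect_equal(back$beta0, fit$beta0)
  expect_equal(back$beta, fit$beta)
  expect_equal(back$beta_prime, fit$beta_prime)
  expect_equal(unname(predict(back, w$pos[1:5])),
               unname(predict(fit, w$pos[1:5])), tolerance = 1e-12)
})

test_that("model accessors behave like standard fitted-model methods", {
  w <- generate_window_sets(bias_spec(radius = 2, n_pos = 50, n_neg = 50,
                                      seed = 30))
  fit <- airliner(w$pos, w$neg)
  expect_length(coef(fit), 1 + 2 * 5)
  expect_length(fitted(fit), 100)
  expect_equal(mean(residuals(fit, type = "response")), 0, tolerance = 0.05)
  s <- summary(fit)
  expect_s3_class(s, "summary.airliner")
  expect_equal(nrow(s$coefficients), 5)
  sim <- simulate(fit, nsim = 2, seed = 4, n_pos = 10, n_neg = 5)
  expect_length(sim, 2)
  expect_length(sim[[1]]$pos, 10)
  expect_identical(simulate(fit, nsim = 2, seed = 4, n_pos = 10, n_neg = 5),
                   sim)
  pdf(NULL)
  expect_invisible(plot(fit))
  expect_invisible(plot(fit, which = "coefficients"))
  dev.off()
})

test_that("multiplicative scoring multiplies per-neighbor coefficients", {
  tab <- data.frame(offset = rep(c(-1L, 1L), each = 4),
                    nucleotide = rep(c("A", "C", "G", "T"), 2),
                    multiplier = c(1, 1, 1, 2, 1, 1, 3, 1))
  sc <- multiplicative_scorer(tab, base_rate = 5)
  # ...TAG...: T at -1 doubles, G at +1 triples -> 5 * 2 * 3
  expect_equal(multiplicative_score(sc, "CCTAGCC"), 30)
  # identity multipliers: score is the base rate for every window
  sc1 <- multiplicative_scorer(
    data.frame(offset = rep(c(-1L, 1L), each = 4),
               nucleotide = rep(c("A", "C", "G", "T"), 2), multiplier = 1),
    base_rate = 7)
  expect_equal(multiplicative_score(sc1, c("CATAGCC", "GGGAGGG")), c(7, 7))
  expect_equal(sc$threshold_percent, 9.6)

  expect_error(
    multiplicative_scorer(data.frame(offset = -1L, nucleotide = "A",
                                     multiplier = 0)),
    class = "configuration_error")
  expect_error(
    multiplicative_scorer(data.frame(offset = 0L, nucleotide = "A",
                                     multiplier = 1)),
    class = "configuration_error")
  # missing (offset, nucleotide) combination surfaces at scoring time
  part <- multiplicative_scorer(data.frame(offset = -1L, nucleotide = "T",
                                           multiplier = 2), base_rate = 5)
  expect_error(multiplicative_score(part, "CCAAGCC"),
               class = "configuration_error")
  expect_error(multiplicative_score(sc, "A"), class = "configuration_error")
})

test_that("scorer tables load from TSV", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("offset\tnucleotide\tmultiplier",
               "-1\tT\t2", "-1\tA\t1", "-1\tC\t1", "-1\tG\t1",
               "1\tG\t3", "1\tA\t1", "1\tC\t1", "1\tT\t1"), f)
  sc <- read_scorer(f, base_rate = 5, id = "toy")
  expect_equal(multiplicative_score(sc, "TAG"), 30)
  expect_equal(predict(sc, "TAG", type = "class"), "edited")
})
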