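# Core fitting machinery: Newton optimization of the ridge-penalized
# binomial log-likelihood, and the airliner() model interface built on it.

log1pexp <- function(x) ifelse(x > 0, x + log1p(exp(-x)), log1p(exp(x)))

#' Ridge-penalized logistic regression by Newton's method
#'
#' Minimizes the penalized negative binomial log-likelihood
#' `-sum(y * eta - log(1 + exp(eta))) + lambda / 2 * sum(beta^2)` with
#' `eta = beta0 + X beta`; the intercept is never penalized. The fit is
#' fully deterministic: it starts at zero and takes damped Newton steps
#' (step-halving on the objective) until the gradient norm drops below
#' `tol` or `max_iter` is reached. With `lambda = 0` on separable data the
#' likelihood has no finite maximizer; the fit then stops at the iteration
#' cap with a warning.
#'
#' This is the optimizer behind [airliner()]; it is exported so that
#' degenerate designs (e.g. all-zero features, where the solution is the
#' closed-form intercept `qlogis(mean(y))`) can be fitted directly.
#'
#' @param X Numeric feature matrix, one row per observation.
#' @param y 0/1 (or logical) response vector.
#' @param lambda L2 penalty on the coefficients, `>= 0`.
#' @param tol Convergence threshold on the gradient max-norm.
#' @param max_iter Newton iteration cap.
#' @return List with `beta0`, `beta`, `iterations`, `gradient_norm`,
#'   `converged`.
#' @export
ridge_logistic <- function(X, y, lambda = 1e-3, tol = 1e-8, max_iter = 500L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)), lambda >= 0)
  n <- nrow(X)
  p <- ncol(X)
  theta <- numeric(p + 1L)  # (beta0, beta)
  Xa <- cbind(1, X)
  pen <- c(0, rep(lambda, p))
  obj <- function(th) {
    eta <- drop(Xa %*% th)
    sum(log1pexp(eta)) - sum(y * eta) + sum(pen * th^2) / 2
  }
  grad <- function(th) {
    eta <- drop(Xa %*% th)
    drop(crossprod(Xa, stats::plogis(eta) - y)) + pen * th
  }
  f <- obj(theta)
  g <- grad(theta)
  iter <- 0L
  while (max(abs(g)) > tol && iter < max_iter) {
    iter <- iter + 1L
    eta <- drop(Xa %*% theta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    H <- crossprod(Xa * w, Xa) + diag(pen, p + 1L)
    step <- tryCatch(solve(H, g), error = function(e) g / max(diag(H)))
    # damped Newton: halve until the objective does not increase
    s <- 1
    repeat {
      cand <- theta - s * step
      fc <- obj(cand)
      if (is.finite(fc) && fc <= f + 1e-12) break
      s <- s / 2
      if (s < 1e-12) {
        cand <- theta
        fc <- f
        break
      }
    }
    if (identical(cand, theta)) break
    theta <- cand
    f <- fc
    g <- grad(theta)
  }
  converged <- max(abs(g)) <= tol
  if (!converged) {
    warning("logistic fit stopped before convergence (gradient max-norm ",
            format(max(abs(g))), " after ", iter, " iterations)",
            call. = FALSE)
  }
  theta <- unname(theta)
  list(beta0 = theta[1], beta = theta[-1], iterations = iter,
       gradient_norm = max(abs(g)), converged = converged)
}

#' Fit the positional-probability logistic model of A-to-I editing
#'
#' Fits a logistic regression that scores a `(2 * radius + 1)`-nt window s
#' centered on an adenosine by
#' \deqn{\log \frac{P(s)}{1 - P(s)} = \beta_0 + \sum_i \beta_i P(s[i], i)
#'   - \sum_i \beta'_i P'(s[i], i),}
#' where P and P' are the positional nucleotide probabilities estimated
#' from the edited and un-edited training windows ([build_profile()]) and
#' the sums run over all window positions, central adenosine included. The
#' minus sign on the P' block is a parameterization -- that feature block is
#' negated before an unconstrained fit -- so the `beta_prime` coefficients
#' are not sign-constrained. A small ridge penalty (default
#' `lambda = 1e-3`) keeps the fit finite even though the central-position
#' feature is collinear with the intercept and separable training sets are
#' common.
#'
#' @param pos Character vector of edited (positive) windows.
#' @param neg Character vector of un-edited (negative) windows of the same
#'   length.
#' @param pseudocount Laplace smoothing for the two profiles.
#' @param lambda Ridge penalty on `(beta, beta_prime)`; the intercept is
#'   unpenalized.
#' @param tol,max_iter Optimizer controls, see [ridge_logistic()].
#' @param ppms Optional precomputed list `list(edited =, unedited =)` of
#'   `"ppm"` matrices to use instead of estimating profiles from `pos` and
#'   `neg` (used e.g. to study profile-estimation leakage).
#' @return An object of class `"airliner"`: a list with `beta0`, `beta`,
#'   `beta_prime`, `radius`, `lambda`, `pseudocount`, the two profiles
#'   (`ppm_edited`, `ppm_unedited`), `fit_info` (iterations, gradient norm,
#'   convergence flag), sample sizes and the training fit
#'   (`fitted_values`, `y`).
#' @examples
#' set.seed(1)
#' spec <- bias_spec(radius = 3, n_pos = 200, n_neg = 200, seed = 7)
#' w <- generate_window_sets(spec)
#' fit <- airliner(w$pos, w$neg)
#' fit
#' predict(fit, w$pos[1:3])
#' @export
airliner <- function(pos, neg, pseudocount = 1, lambda = 1e-3,
                     tol = 1e-8, max_iter = 500L, ppms = NULL) {
  r_pos <- validate_windows(pos, "positive windows")
  r_neg <- validate_windows(neg, "negative windows")
  if (r_pos != r_neg) {
    abort("positive and negative windows have different radii", "shape_error")
  }
  if (is.null(ppms)) {
    ppm_edited <- build_profile(pos, pseudocount)
    ppm_unedited <- build_profile(neg, pseudocount)
  } else {
    ppm_edited <- ppms$edited
    ppm_unedited <- ppms$unedited
    if (ppm_radius(ppm_edited) != r_pos) {
      abort("supplied profiles do not match window radius", "shape_error")
    }
  }
  windows <- c(pos, neg)
  y <- rep(c(1, 0), c(length(pos), length(neg)))
  feats <- featurize(windows, ppm_edited, ppm_unedited)
  L <- 2L * r_pos + 1L
  X <- cbind(feats[, seq_len(L), drop = FALSE],
             -feats[, L + seq_len(L), drop = FALSE])
  fit <- ridge_logistic(X, y, lambda = lambda, tol = tol, max_iter = max_iter)
  eta <- fit$beta0 + drop(X %*% c(fit$beta))
  structure(list(
    beta0 = fit$beta0,
    beta = fit$beta[seq_len(L)],
    beta_prime = fit$beta[L + seq_len(L)],
    radius = r_pos,
    lambda = lambda,
    pseudocount = pseudocount,
    ppm_edited = ppm_edited,
    ppm_unedited = ppm_unedited,
    fit_info = list(iterations = fit$iterations,
                    gradient_norm = fit$gradient_norm,
                    converged = fit$converged,
                    deterministic = TRUE),
    n_pos = length(pos),
    n_neg = length(neg),
    fitted_values = stats::plogis(eta),
    y = y,
    call = match.call()
  ), class = "airliner")
}

model_linear_predictor <- function(object, windows) {
  radius <- validate_windows(windows)
  if (radius != object$radius) {
    abort(sprintf("window radius %d does not match model radius %d",
                  radius, object$radius), "shape_error")
  }
  L <- 2L * radius + 1L
  feats <- featurize(windows, object$ppm_edited, object$ppm_unedited)
  object$beta0 +
    drop(feats[, seq_len(L), drop = FALSE] %*% object$beta) -
    drop(feats[, L + seq_len(L), drop = FALSE] %*% object$beta_prime)
}

#' Predict editing probabilities for new windows
#'
#' @param object Fitted `"airliner"` model.
#' @param newdata Character vector of A-centered windows of the model's
#'   radius. Defaults to the training windows' fitted values when missing.
#' @param type `"response"` (editing probability), `"link"` (logit) or
#'   `"class"` (`"edited"` / `"unedited"` by the strict `> threshold` rule).
#' @param threshold Decision cutoff for `type = "class"`; a probability
#'   exactly equal to it is called unedited.
#' @param ... Unused.
#' @return Numeric vector of probabilities or logits, or a character vector
#'   of class labels.
#' @export
predict.airliner <- function(object, newdata, type = c("response", "link",
                                                       "class"),
                             threshold = 0.5, ...) {
  type <- match.arg(type)
  if (missing(newdata)) {
    if (type == "response") return(object$fitted_values)
    eta <- stats::qlogis(object$fitted_values)
    if (type == "link") return(eta)
    return(ifelse(object$fitted_values > threshold, "edited", "unedited"))
  }
  eta <- model_linear_predictor(object, newdata)
  switch(type,
         link = eta,
         response = stats::plogis(eta),
         class = ifelse(stats::plogis(eta) > threshold, "edited", "unedited"))
}

#' Call windows edited or unedited
#'
#' The decision rule is strict: a window is called `"edited"` only when its
#' predicted editing probability exceeds the threshold, so a probability of
#' exactly 0.5 under the default cutoff is called `"unedited"`.
#'
#' @param model Fitted `"airliner"` model.
#' @param windows Character vector of windows.
#' @param threshold Probability cutoff in (0, 1).
#' @return Character vector of `"edited"` / `"unedited"` labels.
#' @export
classify <- function(model, windows, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) {
    abort("`threshold` must lie strictly inside (0, 1)", "parameter_error")
  }
  predict(model, windows, type = "class", threshold = threshold)
}

#' @export
print.airliner <- function(x, ...) {
  cat("A-to-I editing logistic model (positional-probability features)\n")
  cat(sprintf("  radius %d (%d-nt windows), %d + %d training windows\n",
              x$radius, 2 * x$radius + 1, x$n_pos, x$n_neg))
  cat(sprintf("  ridge lambda = %g, profile pseudocount = %g\n",
              x$lambda, x$pseudocount))
  cat(sprintf("  beta0 = %.4f; %s after %d Newton iterations (|grad| = %.2g)\n",
              x$beta0, if (x$fit_info$converged) "converged" else
                "NOT converged", x$fit_info$iterations,
              x$fit_info$gradient_norm))
  invisible(x)
}

#' @export
coef.airliner <- function(object, ...) {
  L <- 2L * object$radius + 1L
  off <- seq_len(L) - object$radius - 1L
  stats::setNames(c(object$beta0, object$beta, object$beta_prime),
                  c("(Intercept)", paste0("beta[", off, "]"),
                    paste0("beta'[", off, "]")))
}

#' @export
summary.airliner <- function(object, ...) {
  L <- 2L * object$radius + 1L
  off <- seq_len(L) - object$radius - 1L
  tab <- data.frame(offset = off, beta = object$beta,
                    beta_prime = object$beta_prime)
  acc <- mean((object$fitted_values > 0.5) == (object$y == 1))
  structure(list(model = object, coefficients = tab,
                 training_accuracy = acc), class = "summary.airliner")
}

#' @export
print.summary.airliner <- function(x, ...) {
  print(x$model)
  cat(sprintf("  training accuracy at 0.5: %.4f\n", x$training_accuracy))
  cat("\nCoefficients by offset from the central adenosine:\n")
  print(x$coefficients, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
fitted.airliner <- function(object, ...) object$fitted_values

#' @export
residuals.airliner <- function(object, type = c("deviance", "pearson",
                                                "response"), ...) {
  type <- match.arg(type)
  y <- object$y
  mu <- object$fitted_values
  switch(type,
         response = y - mu,
         pearson = (y - mu) / sqrt(mu * (1 - mu)),
         deviance = sign(y - mu) *
           sqrt(-2 * (y * log(mu) + (1 - y) * log(1 - mu))))
}

#' Simulate window sets from a fitted model's profiles
#'
#' Draws windows position-independently from the model's stored edited and
#' un-edited positional profiles -- the model's own generative reading of
#' its training data. Central positions are forced to A.
#'
#' @param object Fitted `"airliner"` model.
#' @param nsim Number of replicate datasets.
#' @param seed Integer seed (required for reproducibility).
#' @param n_pos,n_neg Windows per class in each replicate; default the
#'   training sizes.
#' @param ... Unused.
#' @return A list of `nsim` lists, each with `pos` and `neg` character
#'   vectors.
#' @export
simulate.airliner <- function(object, nsim = 1, seed = 1,
                              n_pos = object$n_pos, n_neg = object$n_neg,
                              ...) {
  with_seed(seed, {
    lapply(seq_len(nsim), function(i) {
      list(pos = sample_profile_windows(object$ppm_edited, n_pos),
           neg = sample_profile_windows(object$ppm_unedited, n_neg))
    })
  })
}

sample_profile_windows <- function(ppm, n) {
  m <- unclass(ppm)
  radius <- attr(ppm, "radius")
  L <- 2L * radius + 1L
  cols <- lapply(seq_len(L), function(i) {
    if (i == radius + 1L) rep("A", n)
    else sample(NUCS, n, replace = TRUE, prob = m[, i])
  })
  do.call(paste0, cols)
}

#' Plot a fitted editing model
#'
#' `which = "profiles"` draws the per-position nucleotide probabilities of
#' the edited (solid) and un-edited (dashed) training profiles -- the
#' neighborhood-preference picture. `which = "coefficients"` draws the two
#' coefficient vectors against the offset from the central adenosine.
#'
#' @param x Fitted `"airliner"` model.
#' @param which `"profiles"` or `"coefficients"`.
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, `x`.
#' @export
plot.airliner <- function(x, which = c("profiles", "coefficients"), ...) {
  which <- match.arg(which)
  off <- seq_len(2L * x$radius + 1L) - x$radius - 1L
  if (which == "profiles") {
    cols <- c(A = "#1b9e77", C = "#d95f02", G = "#7570b3", T = "#e7298a")
    graphics::matplot(off, t(unclass(x$ppm_edited)), type = "l", lty = 1,
                      col = cols, xlab = "offset from central A",
                      ylab = "probability", ylim = c(0, 1),
                      main = "Positional nucleotide preferences", ...)
    graphics::matlines(off, t(unclass(x$ppm_unedited)), lty = 2, col = cols)
    graphics::legend("topright", legend = c(NUCS, "edited", "un-edited"),
                     col = c(cols, "black", "black"),
                     lty = c(1, 1, 1, 1, 1, 2), cex = 0.8, bty = "n")
  } else {
    graphics::matplot(off, cbind(x$beta, x$beta_prime), type = "b", pch = 1:2,
                      lty = 1:2, col = c("black", "grey40"),
                      xlab = "offset from central A", ylab = "coefficient",
                      main = "Model coefficients", ...)
    graphics::legend("topright", legend = c("beta", "beta'"), pch = 1:2,
                     lty = 1:2, col = c("black", "grey40"), bty = "n")
  }
  invisible(x)
}

#' Serialize / restore a fitted model
#'
#' The single JSON document embeds the coefficients, both positional
#' profiles and the fit metadata, version-tagged so later releases can
#' evolve the layout.
#'
#' @param model Fitted `"airliner"` model.
#' @param path File path.
#' @return `write_airliner` returns `path` invisibly; `read_airliner`
#'   returns the restored model.
#' @export
write_airliner <- function(model, path) {
  payload <- list(
    format = "airliner-model", version = 1L,
    beta0 = model$beta0, beta = model$beta, beta_prime = model$beta_prime,
    radius = model$radius, lambda = model$lambda,
    pseudocount = model$pseudocount,
    ppm_edited = list(probs = unclass(model$ppm_edited),
                      n = attr(model$ppm_edited, "n")),
    ppm_unedited = list(probs = unclass(model$ppm_unedited),
                        n = attr(model$ppm_unedited, "n")),
    fit_info = model$fit_info, n_pos = model$n_pos, n_neg = model$n_neg)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_airliner
#' @export
read_airliner <- function(path) {
  p <- jsonlite::fromJSON(path)
  if (!identical(p$format, "airliner-model")) {
    abort("not an airliner model file", "format_error")
  }
  mk_ppm <- function(x) {
    m <- as.matrix(x$probs)
    dimnames(m) <- list(NUCS, NULL)
    structure(m, class = "ppm", radius = p$radius, n = x$n,
              pseudocount = p$pseudocount)
  }
  structure(list(
    beta0 = p$beta0, beta = p$beta, beta_prime = p$beta_prime,
    radius = p$radius, lambda = p$lambda, pseudocount = p$pseudocount,
    ppm_edited = mk_ppm(p$ppm_edited), ppm_unedited = mk_ppm(p$ppm_unedited),
    fit_info = p$fit_info, n_pos = p$n_pos, n_neg = p$n_neg,
    fitted_values = numeric(0), y = numeric(0), call = NULL
  ), class = "airliner")
}
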