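## Feeding-outcome classifier: L2-penalized logistic regression with
## class-balanced weights on pre-stimulus behavior proportions, validated
## by bootstrap resampling and a shuffle (permutation) null.
##
## The fit is a Newton/IRLS optimizer of the penalized log-likelihood
##   sum_i w_i [y_i log p_i + (1 - y_i) log(1 - p_i)] - lambda/2 ||beta||^2
## (intercept unpenalized), with balanced weights w_i = n / (2 n_class(i)).
## lambda = 1 matches the common C = 1 default of liblinear-style solvers.

#' Build the predictor table for feeding prediction
#'
#' Per-animal raw-flag time proportions of the four behaviors over a
#' window relative to a stimulus onset (typically the 2 min after the
#' light pulse), plus the engorged outcome.  Animals without an outcome
#' are dropped with a warning.
#'
#' @param x A `cohort` with `engorged` metadata.
#' @param window `c(t0, t1)` seconds relative to the pulse onset.
#' @param channel,pulse Stimulus pulse defining `t = 0`.
#' @return Data frame of class `"predictor_table"` with columns
#'   `animal_id`, `groom`, `walk`, `probe`, `fly`, `engorged`.
#' @export
build_predictor_table <- function(x, window = c(0, 120), channel = "light",
                                  pulse = 1L) {
  if (window[2] <= window[1]) stop("empty predictor window")
  x <- align_to_stimulus(x, channel, pulse)
  props <- vapply(BEHAVIORS, function(b) animal_response(x, b, window),
                  numeric(length(x$ethograms)))
  out <- data.frame(animal_id = x$meta$animal_id, props,
                    engorged = as.integer(x$meta$engorged))
  miss <- is.na(out$engorged)
  if (any(miss)) {
    warning("dropping ", sum(miss), " animal(s) with missing outcome")
    out <- out[!miss, ]
  }
  rownames(out) <- NULL
  class(out) <- c("predictor_table", "data.frame")
  out
}

## Ridge logistic IRLS.  X: n x p (no intercept column), y in {0,1},
## lambda: L2 penalty on the slopes.  Returns coefficients (intercept
## first) at the penalized-likelihood optimum (relative tolerance 1e-8).
ridge_logistic <- function(X, y, lambda = 1, balanced = TRUE,
                           max_iter = 100L, tol = 1e-8) {
  X1 <- cbind(`(Intercept)` = 1, as.matrix(X))
  n <- nrow(X1); p <- ncol(X1)
  w <- rep(1, n)
  if (balanced) {
    tab <- c(sum(y == 0), sum(y == 1))
    if (any(tab == 0)) stop("both outcome classes must be present")
    w <- n / (2 * tab[y + 1])
  }
  pen <- diag(c(0, rep(lambda, p - 1)), p)
  beta <- rep(0, p)
  dev_old <- Inf
  for (it in seq_len(max_iter)) {
    eta <- drop(X1 %*% beta)
    mu <- plogis(eta)
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    grad <- drop(crossprod(X1, w * (y - mu))) - pen %*% beta
    H <- crossprod(X1 * (w * mu * (1 - mu)), X1) + pen
    step <- tryCatch(solve(H, grad), error = function(e)
      solve(H + diag(1e-8, p), grad))
    beta <- beta + drop(step)
    dev <- -2 * sum(w * (y * log(mu) + (1 - y) * log(1 - mu))) +
      lambda * sum(beta[-1]^2)
    if (abs(dev - dev_old) < tol * (abs(dev) + tol)) break
    dev_old <- dev
  }
  names(beta) <- colnames(X1)
  beta
}

predict_logistic <- function(beta, X) {
  plogis(drop(cbind(1, as.matrix(X)) %*% beta))
}

#' Balanced accuracy
#'
#' Mean of sensitivity and specificity at a probability threshold of 0.5;
#' the chance level is 0.5 regardless of class imbalance, which is why it
#' is the headline performance statistic for the class-weighted model.
#'
#' @param y True 0/1 outcomes.
#' @param p Predicted probabilities.
#' @return Scalar in `[0, 1]`.
#' @export
balanced_accuracy <- function(y, p) {
  yhat <- as.integer(p >= 0.5)
  mean(c(mean(yhat[y == 1] == 1), mean(yhat[y == 0] == 0)))
}

table_xy <- function(table) {
  list(X = as.matrix(table[, BEHAVIORS, drop = FALSE]),
       y = as.integer(table$engorged))
}

#' Fit the feeding classifier and cross-validate it
#'
#' Fits the class-balanced ridge logistic model on the full table and
#' scores it by leave-one-out cross-validation (balanced accuracy of the
#' held-out predictions at threshold 0.5).  Raw accuracy and AUROC are
#' reported alongside.
#'
#' @param table A [build_predictor_table()] result.
#' @param lambda L2 penalty (default 1).
#' @return List with `coefficients`, `train` (in-sample balanced
#'   accuracy), `loo` (LOO-CV balanced accuracy), `loo_accuracy`,
#'   `loo_auc`.
#' @export
fit_and_score <- function(table, lambda = 1) {
  d <- table_xy(table)
  if (length(unique(d$y)) < 2) stop("both outcome classes must be present")
  beta <- ridge_logistic(d$X, d$y, lambda)
  p_train <- predict_logistic(beta, d$X)
  n <- length(d$y)
  p_loo <- vapply(seq_len(n), function(i) {
    if (length(unique(d$y[-i])) < 2) return(mean(d$y[-i]))
    b <- ridge_logistic(d$X[-i, , drop = FALSE], d$y[-i], lambda)
    predict_logistic(b, d$X[i, , drop = FALSE])
  }, 0)
  auc <- {
    r <- rank(p_loo)
    n1 <- sum(d$y == 1); n0 <- n - n1
    (sum(r[d$y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  list(coefficients = beta,
       train = balanced_accuracy(d$y, p_train),
       loo = balanced_accuracy(d$y, p_loo),
       loo_accuracy = mean((p_loo >= 0.5) == (d$y == 1)),
       loo_auc = auc)
}

#' Bootstrap distribution of classifier performance
#'
#' Resamples animals with replacement, refits the model on each resample
#' and scores it (in-sample balanced accuracy, the same statistic used
#' for the observed model and the shuffle null).  Resamples containing a
#' single outcome class are redrawn.
#'
#' @param table A [build_predictor_table()] result.
#' @param B Number of bootstrap resamples (default 10000).
#' @param seed Integer RNG seed.
#' @param lambda L2 penalty.
#' @return Numeric vector of `B` performances.
#' @export
bootstrap_performance <- function(table, B = 10000L, seed = 0L, lambda = 1) {
  d <- table_xy(table)
  n <- length(d$y)
  set.seed(seed)
  vapply(seq_len(B), function(b) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(d$y[idx])) == 2) break
    }
    beta <- ridge_logistic(d$X[idx, , drop = FALSE], d$y[idx], lambda)
    balanced_accuracy(d$y[idx], predict_logistic(beta, d$X[idx, ,
                                                           drop = FALSE]))
  }, 0)
}

#' Shuffle-null distribution of classifier performance
#'
#' Permutes the engorgement outcomes across animals (predictors
#' untouched), refits and scores each permuted dataset.  The resulting
#' distribution is the chance-level reference for [significance()].
#'
#' @param table A [build_predictor_table()] result.
#' @param S Number of shuffles (default 10000).
#' @param seed Integer RNG seed.
#' @param lambda L2 penalty.
#' @return Numeric vector of `S` performances.
#' @export
shuffle_null <- function(table, S = 10000L, seed = 0L, lambda = 1) {
  d <- table_xy(table)
  n <- length(d$y)
  set.seed(seed)
  vapply(seq_len(S), function(s) {
    ys <- d$y[sample.int(n)]
    beta <- ridge_logistic(d$X, ys, lambda)
    balanced_accuracy(ys, predict_logistic(beta, d$X))
  }, 0)
}

#' Significance of observed performance against a null distribution
#'
#' The z statistic `(observed - mean(null)) / sd(null)` with a one-sided
#' normal upper-tail p value; the empirical percentile of the observed
#' value in the null is reported alongside.  An alternative
#' distribution-vs-distribution z (bootstrap mean vs null) is available
#' via `boot`.
#'
#' @param observed Observed performance (scalar).
#' @param null Numeric vector, the shuffle-null distribution.
#' @param boot Optional bootstrap distribution; when given, `z_boot`
#'   compares its mean to the null using both spreads.
#' @return List with `z`, `p`, `percentile` (and `z_boot`, `p_boot` when
#'   `boot` is given).
#' @export
significance <- function(observed, null, boot = NULL) {
  if (length(unique(null)) < 2) stop("null distribution has no variance")
  z <- (observed - mean(null)) / sd(null)
  out <- list(z = z, p = pnorm(z, lower.tail = FALSE),
              percentile = mean(null < observed))
  if (!is.null(boot)) {
    s <- sqrt(sd(null)^2 + sd(boot)^2)
    out$z_boot <- (mean(boot) - mean(null)) / s
    out$p_boot <- pnorm(out$z_boot, lower.tail = FALSE)
  }
  out
}

#' Full feeding-prediction significance report
#'
#' Convenience wrapper: fit and LOO-score the model, draw the bootstrap
#' and shuffle-null distributions, and compute the z test.
#'
#' @param table A [build_predictor_table()] result.
#' @param B,S Bootstrap and shuffle counts.
#' @param seed Integer RNG seed (bootstrap uses `seed`, shuffles
#'   `seed + 1`).
#' @param lambda L2 penalty.
#' @return List with `observed` (in-sample balanced accuracy), `loo`,
#'   `z`, `p`, `percentile`, `boot`, `null`.
#' @export
feeding_report <- function(table, B = 10000L, S = 10000L, seed = 0L,
                           lambda = 1) {
  fit <- fit_and_score(table, lambda)
  boot <- bootstrap_performance(table, B, seed = seed, lambda = lambda)
  null <- shuffle_null(table, S, seed = seed + 1L, lambda = lambda)
  sig <- significance(fit$train, null, boot)
  list(observed = fit$train, loo = fit$loo, loo_auc = fit$loo_auc,
       coefficients = fit$coefficients, z = sig$z, p = sig$p,
       percentile = sig$percentile, z_boot = sig$z_boot,
       p_boot = sig$p_boot, boot = boot, null = null)
}
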