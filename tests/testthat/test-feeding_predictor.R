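## Direct predictor tables for classifier tests (no simulation needed).
synth_table <- function(n = 200, effect = 0, p_feed = 0.4, seed = 1) {
  set.seed(seed)
  X <- cbind(groom = runif(n, 0, 0.4), walk = runif(n, 0, 0.6),
             probe = runif(n, 0, 0.6), fly = runif(n, 0, 0.2))
  y <- rbinom(n, 1, p_feed)
  X[y == 1, "probe"] <- pmin(X[y == 1, "probe"] + effect, 1)
  out <- data.frame(animal_id = sprintf("t%03d", seq_len(n)), X,
                    engorged = y)
  class(out) <- c("predictor_table", "data.frame")
  out
}

test_that("predictor table holds window proportions and outcomes", {
  n <- 3600                                       # 120 s at 30 fps
  probe_all <- ethogram("full", flag_mat(probe = TRUE, n = 2 * n), fps = 30)
  probe_none <- ethogram("idle", flag_mat(n = 2 * n), fps = 30)
  stim <- stimulus_series(list(light = data.frame(onset_s = 0.5,
                                                  offset_s = 5.5,
                                                  magnitude = 1)))
  meta <- data.frame(animal_id = c("full", "idle"), sex = "f",
                     condition = "c", engorged = c(TRUE, FALSE))
  co <- cohort(list(probe_all, probe_none), stim, meta)
  tab <- build_predictor_table(co, window = c(0, 120))
  expect_equal(tab$probe, c(1, 0))
  expect_equal(tab$engorged, c(1L, 0L))
  expect_error(build_predictor_table(co, window = c(10, 10)), "empty")
  ## missing outcomes are dropped with a warning
  co$meta$engorged[2] <- NA
  expect_warning(tab2 <- build_predictor_table(co, window = c(0, 120)),
                 "missing outcome")
  expect_equal(nrow(tab2), 1L)
  ## proportions match a direct frame count on random ethograms
  set.seed(30)
  co3 <- tiny_cohort(n_animals = 3, n = 4000)
  co3$stimuli <- stimulus_series(list(light = data.frame(
    onset_s = 10, offset_s = 11, magnitude = 1)))
  tab3 <- build_predictor_table(co3, window = c(0, 100))
  for (i in 1:3) {
    e <- co3$ethograms[[i]]
    fr <- (10 * 30 + 1):(110 * 30)
    expect_equal(tab3$walk[i], sum(e$flags[fr, "walk"]) / length(fr))
  }
})

test_that("the ridge logistic fit reaches the penalized optimum", {
  skip_if_not_installed("glmnet")
  tab <- synth_table(150, effect = 0.1)
  X <- as.matrix(tab[, c("groom", "walk", "probe", "fly")])
  y <- tab$engorged
  n <- length(y)
  w <- n / (2 * c(sum(y == 0), sum(y == 1)))[y + 1]
  g <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                      lambda = 1 / n, weights = w / mean(w),
                      standardize = FALSE, thresh = 1e-12)
  mine <- ethopersist:::ridge_logistic(X, y, lambda = 1)
  expect_equal(unname(mine), as.numeric(glmnet::coef.glmnet(g)),
               tolerance = 1e-5)
})

test_that("classifier scoring behaves at the extremes", {
  ## perfectly separable: probe alone decides feeding
  sep <- synth_table(80, effect = 0)
  sep$probe <- ifelse(sep$engorged == 1, 0.9, 0.05)
  fit <- fit_and_score(sep)
  expect_equal(fit$loo, 1)
  expect_equal(fit$loo_auc, 1)
  ## outcome independent of predictors: LOO near chance
  null <- synth_table(200, effect = 0, seed = 9)
  fitn <- fit_and_score(null)
  expect_lt(abs(fitn$loo - 0.5), 0.1)
  ## duplicating every row doubles the likelihood, so the identical fit
  ## is recovered when the fixed penalty is scaled in proportion
  dup <- rbind(synth_table(60, seed = 4), synth_table(60, seed = 4))
  class(dup) <- class(sep)
  expect_equal(fit_and_score(dup, lambda = 2)$coefficients,
               fit_and_score(synth_table(60, seed = 4),
                             lambda = 1)$coefficients,
               tolerance = 1e-6)
  single <- synth_table(50, p_feed = 0)
  expect_error(fit_and_score(single), "both outcome classes")
})

test_that("bootstrap and shuffle distributions are reproducible and sized", {
  tab <- synth_table(100, effect = 0.2, seed = 5)
  b1 <- bootstrap_performance(tab, B = 1, seed = 11)
  expect_length(b1, 1L)
  b2 <- bootstrap_performance(tab, B = 50, seed = 11)
  expect_identical(b2, bootstrap_performance(tab, B = 50, seed = 11))
  s1 <- shuffle_null(tab, S = 1, seed = 12)
  expect_length(s1, 1L)
  s2 <- shuffle_null(tab, S = 50, seed = 12)
  expect_identical(s2, shuffle_null(tab, S = 50, seed = 12))
  expect_false(identical(s2, shuffle_null(tab, S = 50, seed = 13)))
})

test_that("separable data concentrate the bootstrap near perfect scores", {
  sep <- synth_table(80)
  sep$probe <- ifelse(sep$engorged == 1, 0.9, 0.05)
  b <- bootstrap_performance(sep, B = 100, seed = 2)
  expect_gt(median(b), 0.99)
})

test_that("the shuffle null sits at its in-sample chance level", {
  ## in-sample balanced accuracy of a 4-predictor model on shuffled
  ## labels sits somewhat above 0.5 by overfitting; the null captures
  ## exactly that reference level
  tab <- synth_table(150, effect = 0, seed = 6)
  null <- shuffle_null(tab, S = 200, seed = 3)
  expect_gt(median(null), 0.5)
  expect_lt(median(null), 0.68)
  ## and the observed score on independent labels is within the null
  fit <- fit_and_score(tab)
  expect_gt(mean(null >= fit$train), 0.01)
})

test_that("significance arithmetic follows the normal z-test", {
  null <- c(rep(0.5, 50), rep(0.6, 50))
  m <- mean(null); s <- sd(null)
  sig <- significance(m, null)
  expect_equal(sig$z, 0)
  expect_equal(sig$p, 0.5)
  sig3 <- significance(m + 3 * s, null)
  expect_equal(sig3$p, pnorm(3, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(sig3$p, 0.00135, tolerance = 1e-2)
  expect_error(significance(0.5, rep(0.5, 10)), "variance")
  ## dual-distribution variant
  sig2 <- significance(m, null, boot = null + 0.2)
  expect_gt(sig2$z_boot, 0)
})

test_that("normal-tail p and empirical percentile agree on synthetic data", {
  tab <- synth_table(150, effect = 0.15, seed = 8)
  fit <- fit_and_score(tab)
  null <- shuffle_null(tab, S = 400, seed = 21)
  sig <- significance(fit$train, null)
  emp_p <- mean(null >= fit$train)
  ## the two p values agree within a factor of ~2 when not degenerate
  if (emp_p > 1 / 400)
    expect_lt(abs(log(sig$p / emp_p)), log(3.5))
  expect_equal(sig$percentile, 1 - emp_p, tolerance = 0.01)
})

test_that("the full feeding report assembles every component", {
  tab <- synth_table(90, effect = 0.25, seed = 10)
  rep <- feeding_report(tab, B = 30, S = 30, seed = 1)
  expect_length(rep$boot, 30L)
  expect_length(rep$null, 30L)
  expect_true(rep$p >= 0 && rep$p <= 1)
  expect_named(rep$coefficients,
               c("(Intercept)", "groom", "walk", "probe", "fly"))
})
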