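test_that("default configuration encodes the assay conditions", {
  cfg <- default_config()
  expect_identical(sort(names(cfg$states)),
                   sort(c("rest", "global_search", "local_search",
                          "engorge")))
  expect_equal(cfg$n_animals, 70L)
  expect_equal(cfg$duration_s, 1200)             # 20-min trial
  light <- cfg$stimuli$channels$light
  expect_equal(light$offset_s - light$onset_s, 5)  # 5 s pulse
  tr <- Filter(function(t) t$channel == "light", cfg$triggers)[[1]]
  expect_equal(tr$half_life_s, 234)              # 3.9 min probing decay
  expect_identical(cfg, default_config())        # two calls equal
  expect_silent(ethopersist:::validate_config(cfg))
})

test_that("invalid configurations are rejected", {
  cfg <- default_config()
  cfg$states$rest$emission[1] <- -0.1
  expect_error(ethopersist:::validate_config(cfg), "emission")
  cfg2 <- default_config()
  cfg2$triggers[[1]]$half_life_s <- -5
  expect_error(ethopersist:::validate_config(cfg2), "half-life")
  cfg3 <- default_config()
  cfg3$states$rest$mean_bout_s[2] <- 0
  expect_error(ethopersist:::validate_config(cfg3), "bout")
})

test_that("simulation is bit-reproducible under a fixed seed", {
  cfg <- default_config()
  cfg$n_animals <- 4L; cfg$duration_s <- 120; cfg$seed <- 99L
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$cohort$ethograms[[3]]$flags,
                   s2$cohort$ethograms[[3]]$flags)
  expect_identical(s1$cohort$ethograms[[2]]$track,
                   s2$cohort$ethograms[[2]]$track)
  expect_identical(s1$latent, s2$latent)
  cfg$seed <- 100L
  s3 <- simulate_cohort(cfg)
  expect_false(identical(s1$cohort$ethograms[[1]]$flags,
                         s3$cohort$ethograms[[1]]$flags))
})

test_that("latent traces match the emitted ethograms frame for frame", {
  cfg <- default_config()
  cfg$n_animals <- 3L; cfg$duration_s <- 200; cfg$seed <- 5L
  sim <- simulate_cohort(cfg)
  for (i in 1:3) {
    expect_equal(length(sim$latent[[i]]),
                 n_frames(sim$cohort$ethograms[[i]]))
    expect_true(all(sim$latent[[i]] %in% names(cfg$states)))
  }
})

test_that("zero trigger probability leaves behavior at baseline", {
  cfg <- default_config()
  cfg$n_animals <- 40L; cfg$seed <- 21L; cfg$include_track <- FALSE
  cfg$duration_s <- 600
  cfg$triggers <- lapply(cfg$triggers, function(t) {
    t$entry_prob <- 0; t
  })
  cfg$feeding$coef <- 0
  cfg$feeding$intercept <- qlogis(1e-6)    # keep engorge out of the latents
  sim <- simulate_cohort(cfg)
  expect_true(all(unlist(sim$latent) == "rest"))
  co <- align_to_stimulus(sim$cohort, "light", 1)
  pre <- mean(animal_response(co, "probe", c(-120, 0)))
  post <- mean(animal_response(co, "probe", c(0, 120)))
  expect_lt(abs(post - pre), 0.02)
})

test_that("baseline emission probabilities are recovered without triggers", {
  cfg <- default_config()
  cfg$n_animals <- 30L; cfg$duration_s <- 300; cfg$seed <- 31L
  cfg$include_track <- FALSE
  cfg$triggers <- list()
  cfg$feeding$intercept <- qlogis(1e-6)
  sim <- simulate_cohort(cfg)
  lab <- do.call(rbind, lapply(sim$cohort$ethograms, function(e)
    table(resolve_precedence(e$flags)) / n_frames(e)))
  got <- colMeans(lab)[c("groom", "walk", "probe", "fly", "none")]
  want <- cfg$states$rest$emission
  expect_true(all(abs(got - want) < 0.02),
              label = paste("proportions", paste(round(got, 3),
                                                 collapse = ",")))
})

test_that("triggered-state occupancy decays with the configured half-life", {
  cfg <- default_config()
  cfg$n_animals <- 500L; cfg$seed <- 41L; cfg$include_track <- FALSE
  cfg$duration_s <- 420
  tau <- 60
  cfg$states$global_search$next_state <- c(rest = 1)
  cfg$triggers <- list(list(channel = "light", target_state = "global_search",
                            entry_prob = 0.9, half_life_s = tau))
  cfg$stimuli <- stimulus_series(list(
    light = data.frame(onset_s = 60, offset_s = 65, magnitude = 1)))
  cfg$feeding$intercept <- qlogis(1e-6)
  sim <- simulate_cohort(cfg)
  fps <- cfg$fps
  occ_at <- function(t_s) {
    fr <- as.integer((60 + t_s) * fps) + 1L
    mean(vapply(sim$latent, function(l) l[fr] == "global_search", TRUE))
  }
  ts <- seq(5, 240, by = 5)
  occ <- vapply(ts, occ_at, 0)
  fit <- lm(log(occ) ~ ts)
  tau_hat <- -log(2) / coef(fit)[2]
  expect_lt(abs(tau_hat - tau) / tau, 0.15)
})

test_that("feeding prevalence follows the logistic feeding model", {
  cfg <- default_config()
  cfg$n_animals <- 400L; cfg$duration_s <- 120; cfg$seed <- 51L
  cfg$include_track <- FALSE
  cfg$triggers <- list()
  cfg$stimuli <- stimulus_series(list(
    heat = data.frame(onset_s = 60, offset_s = 65, magnitude = 10)))
  cfg$feeding <- list(intercept = qlogis(0.3), coef = 0, window_s = 60,
                      search_state = "local_search",
                      engorge_state = "engorge", channel = "heat")
  sim <- simulate_cohort(cfg)
  prev <- mean(sim$cohort$meta$engorged)
  se <- sqrt(0.3 * 0.7 / 400)
  expect_lt(abs(prev - 0.3), 4 * se)
})

test_that("additivity scenarios build the constructed response ratios", {
  for (mode in c("additive", "suppressive", "enhanced")) {
    cfg <- default_config(); cfg$n_animals <- 10L
    sc <- make_additivity_scenario(mode, cfg)
    expect_equal(sort(unique(sc$meta$condition)), c("A", "AB", "B"))
    res <- cohort_additivity(sc)
    want <- switch(mode, additive = 100, suppressive = 50, enhanced = 150)
    expect_equal(res$median_pct, want)
  }
})

test_that("analytic decay curves obey the half-life algebra", {
  cv <- make_decay_curve(0.1, 0.7, 60, duration_s = 300)
  at <- function(t) cv$values[which.min(abs(cv$times_s - t))]
  expect_equal(at(0), 0.7)
  expect_equal(at(60), 0.1 + (0.7 - 0.1) / 2)     # midway at t = tau
  expect_lt(abs(at(299) - 0.1), 0.02)             # back to baseline
  expect_equal(unique(cv$values[cv$times_s < 0]), 0.1)
  expect_error(make_decay_curve(0.5, 0.2, 60), "baseline")
  expect_error(make_decay_curve(0, 0.5, -3), "tau")
})
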