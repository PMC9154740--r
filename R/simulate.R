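## Synthetic cohort generator.
##
## Latent dynamics are semi-Markov: each animal sits in a baseline state
## until a trigger pulse, enters the trigger's target state with a stated
## entry probability, dwells there for an exponential time (half-life
## tau1/2, rate ln2/tau1/2 per second), then moves through the state's
## next-state distribution (e.g. global search can hand over to local
## search) until it falls back to baseline.  Within a state, behaviors are
## emitted as alternating bouts: bout type is drawn so that stationary
## per-frame time fractions equal the state's emission probabilities, and
## bout durations are geometric with the stated per-behavior means.
## Engorgement is drawn from a logistic model on local-search occupancy in
## a window before the heat pulse; engorged animals enter an absorbing
## engorge state at the heat pulse offset.

state_spec <- function(emission, mean_bout_s, mean_speed_px_s,
                       probe_walk_frac = 0, half_life_s = Inf,
                       next_state = NULL) {
  stopifnot(abs(sum(emission) - 1) < 1e-8, all(emission >= 0),
            all(mean_bout_s > 0), half_life_s > 0)
  list(emission = emission[CATEGORIES_EMIT],
       mean_bout_s = mean_bout_s[CATEGORIES_EMIT],
       mean_speed_px_s = mean_speed_px_s[CATEGORIES_EMIT],
       probe_walk_frac = probe_walk_frac,
       half_life_s = half_life_s, next_state = next_state)
}

CATEGORIES_EMIT <- c("groom", "walk", "probe", "fly", "none")

#' Default synthetic-cohort configuration
#'
#' Encodes the assay conditions the generator emulates: cohorts of 70
#' animals recorded for 20 min at 30 frames/s; a 5 s light pulse (fictive
#' CO2) at 300 s that triggers a persistent search state whose probing
#' response decays with a half-life of 234 s (3.9 min); a 5 s heat pulse at
#' 900 s that triggers a brief local-search state (half-life 24 s, i.e.
#' 0.4 min); four latent states (`rest`, `global_search`, `local_search`,
#' `engorge`); and a logistic feeding model in which the probability of
#' engorging increases with local-search occupancy during the 2 min before
#' the heat pulse.
#'
#' @return A named list of class `"etho_config"`; see the package vignette
#'   for the meaning and units of every field.
#' @export
default_config <- function() {
  ## Emission profiles are deliberately extreme, as classified behavior in
  ## this assay is: a resting mosquito is still apart from grooming bursts,
  ## global search is dominated by flight and fast walking, local search by
  ## sustained surface probing, and an engorging mosquito probes nearly
  ## continuously while motionless.  Each state also sits firmly on one
  ## side of every minimum-exhibit cutoff so cutoff zeroing acts uniformly
  ## within a state.
  states <- list(
    rest = state_spec(
      emission = c(groom = 0.15, walk = 0.02, probe = 0.005, fly = 0.005,
                   none = 0.82),
      mean_bout_s = c(groom = 4, walk = 1.5, probe = 1, fly = 0.5,
                      none = 10),
      mean_speed_px_s = c(groom = 1, walk = 8, probe = 2, fly = 60,
                          none = 0.2),
      probe_walk_frac = 0),
    global_search = state_spec(
      emission = c(groom = 0.01, walk = 0.30, probe = 0.08, fly = 0.41,
                   none = 0.20),
      mean_bout_s = c(groom = 2, walk = 2, probe = 1.5, fly = 2, none = 1.5),
      mean_speed_px_s = c(groom = 1, walk = 15, probe = 3, fly = 80,
                          none = 0.5),
      probe_walk_frac = 0.5, half_life_s = 234,
      next_state = c(local_search = 0.5, rest = 0.5)),
    local_search = state_spec(
      emission = c(groom = 0.01, walk = 0.25, probe = 0.55, fly = 0.01,
                   none = 0.18),
      mean_bout_s = c(groom = 2, walk = 1.5, probe = 3, fly = 0.5, none = 2),
      mean_speed_px_s = c(groom = 1, walk = 6, probe = 2, fly = 60,
                          none = 0.3),
      probe_walk_frac = 0.5, half_life_s = 90,
      next_state = c(rest = 1)),
    engorge = state_spec(
      emission = c(groom = 0.01, walk = 0.01, probe = 0.85, fly = 0,
                   none = 0.13),
      mean_bout_s = c(groom = 2, walk = 1, probe = 10, fly = 0.5, none = 3),
      mean_speed_px_s = c(groom = 0.5, walk = 2, probe = 0.5, fly = 10,
                          none = 0.1),
      probe_walk_frac = 0))
  structure(list(
    n_animals = 70L, fps = 30, duration_s = 1200, seed = 0L,
    include_track = TRUE,
    baseline_state = "rest",
    states = states,
    triggers = list(
      list(channel = "light", target_state = "global_search",
           entry_prob = 0.9, half_life_s = 234),
      list(channel = "heat", target_state = "local_search",
           entry_prob = 0.8, half_life_s = 24)),
    stimuli = stimulus_series(list(
      light = data.frame(onset_s = 300, offset_s = 305, magnitude = 1),
      heat = data.frame(onset_s = 900, offset_s = 905, magnitude = 10))),
    feeding = list(intercept = qlogis(0.15), coef = 3, window_s = 120,
                   search_state = "local_search", engorge_state = "engorge",
                   channel = "heat")),
    class = "etho_config")
}

validate_config <- function(cfg) {
  stopifnot(cfg$n_animals >= 1, cfg$fps > 0, cfg$duration_s > 0)
  if (!cfg$baseline_state %in% names(cfg$states))
    stop("baseline_state not among states")
  for (nm in names(cfg$states)) {
    s <- cfg$states[[nm]]
    if (any(s$emission < 0) || abs(sum(s$emission) - 1) > 1e-8)
      stop("state ", nm, ": emission must be probabilities summing to 1")
    if (any(s$mean_bout_s <= 0)) stop("state ", nm, ": negative bout length")
    if (s$half_life_s <= 0) stop("state ", nm, ": half-life must be > 0")
    if (!is.null(s$next_state) &&
        !all(names(s$next_state) %in% names(cfg$states)))
      stop("state ", nm, ": unknown next_state")
  }
  for (tr in cfg$triggers) {
    if (!tr$target_state %in% names(cfg$states))
      stop("trigger targets unknown state ", tr$target_state)
    if (tr$entry_prob < 0 || tr$entry_prob > 1)
      stop("trigger entry_prob outside [0,1]")
    if (tr$half_life_s <= 0) stop("trigger half-life must be > 0")
  }
  invisible(TRUE)
}

## Simulate one animal's latent segments (state, start_s, end_s).
## Triggers always apply at their pulse onset (resetting any current
## state); chain entries use the state's own half-life, trigger entries
## the trigger's.
simulate_latent <- function(cfg) {
  ev <- list()
  for (tr in cfg$triggers) {
    ch <- cfg$stimuli$channels[[tr$channel]]
    if (is.null(ch)) next
    for (j in seq_len(nrow(ch)))
      if (ch$onset_s[j] < cfg$duration_s)
        ev[[length(ev) + 1L]] <- list(t = ch$onset_s[j], tr = tr)
  }
  ev <- ev[order(vapply(ev, `[[`, 0, "t"))]
  segs <- list()
  push <- function(state, a, b)
    segs[[length(segs) + 1L]] <<- list(state = state, start = a, end = b)
  t <- 0; state <- cfg$baseline_state; hl <- Inf
  advance <- function(t, state, hl, t_stop) {
    ## run the semi-Markov chain from t to t_stop without triggers
    while (t < t_stop) {
      if (!is.finite(hl)) { push(state, t, t_stop); t <- t_stop; break }
      d <- rexp(1, log(2) / hl)
      end <- min(t + d, t_stop)
      push(state, t, end)
      t <- end
      if (t < t_stop) {
        nx <- cfg$states[[state]]$next_state
        state <- if (is.null(nx)) cfg$baseline_state
                 else names(nx)[sample.int(length(nx), 1L, prob = nx)]
        hl <- cfg$states[[state]]$half_life_s
        if (state == cfg$baseline_state) hl <- Inf
      }
    }
    list(t = t, state = state, hl = hl)
  }
  for (e in ev) {
    st <- advance(t, state, hl, e$t)
    t <- st$t; state <- st$state; hl <- st$hl
    if (runif(1) < e$tr$entry_prob) {
      state <- e$tr$target_state
      hl <- e$tr$half_life_s
    }
  }
  st <- advance(t, state, hl, cfg$duration_s)
  segs
}

## Expand latent segments to a per-frame state vector (length n frames).
segments_to_frames <- function(segs, fps, n) {
  out <- character(n)
  for (s in segs) {
    a <- floor(s$start * fps) + 1L
    b <- min(ceiling(s$end * fps), n)
    if (b >= a) out[a:b] <- s$state
  }
  out
}

## Emit behavior bouts for a run of n frames in one state.  Returns list
## with integer labels (index into CATEGORIES_EMIT) and a per-frame
## co-walking flag for probe bouts.
emit_state_run <- function(state, n, fps) {
  mb <- pmax(state$mean_bout_s * fps, 1)      # mean bout length in frames
  q <- state$emission / mb
  if (sum(q) == 0) q <- c(0, 0, 0, 0, 1)      # degenerate: emit none
  q <- q / sum(q)
  lab <- integer(0); cow <- logical(0); got <- 0L
  exp_len <- sum(q * mb)
  while (got < n) {
    k <- max(8L, ceiling((n - got) / exp_len * 1.5))
    idx <- sample.int(5L, k, replace = TRUE, prob = q)
    dur <- 1L + rgeom(k, pmin(1, 1 / mb[idx]))
    co <- idx == 3L & runif(k) < state$probe_walk_frac
    lab <- c(lab, rep.int(idx, dur))
    cow <- c(cow, rep.int(co, dur))
    got <- length(lab)
  }
  list(lab = lab[seq_len(n)], cow = cow[seq_len(n)])
}

#' Simulate a synthetic cohort with latent ground truth
#'
#' Generates a [cohort()] of per-frame ethograms from the semi-Markov
#' latent-state model described in [default_config()], together with the
#' per-frame latent state of every animal.  A fixed seed makes the output
#' bit-reproducible; all randomness is drawn from a single stream seeded
#' from `config$seed`.
#'
#' @param config A configuration list as returned by [default_config()]
#'   (possibly modified).
#' @return A list with elements `cohort` (a [cohort()]) and `latent` (a
#'   list, per animal, of per-frame latent state names).
#' @export
simulate_cohort <- function(config = default_config()) {
  cfg <- config
  validate_config(cfg)
  set.seed(cfg$seed)
  n <- as.integer(round(cfg$duration_s * cfg$fps))
  heat_ch <- cfg$stimuli$channels[[cfg$feeding$channel]]
  eths <- vector("list", cfg$n_animals)
  latent <- vector("list", cfg$n_animals)
  engorged <- logical(cfg$n_animals)
  for (i in seq_len(cfg$n_animals)) {
    segs <- simulate_latent(cfg)
    lstate <- segments_to_frames(segs, cfg$fps, n)
    ## feeding outcome from local-search occupancy before the heat pulse
    occ <- 0
    heat_in_record <- !is.null(heat_ch) && nrow(heat_ch) &&
      heat_ch$onset_s[1] < cfg$duration_s
    if (heat_in_record) {
      on <- heat_ch$onset_s[1]
      w0 <- max(0, on - cfg$feeding$window_s)
      fr <- (floor(w0 * cfg$fps) + 1L):min(max(floor(on * cfg$fps), 1L), n)
      occ <- mean(lstate[fr] == cfg$feeding$search_state)
    }
    p_feed <- plogis(cfg$feeding$intercept + cfg$feeding$coef * occ)
    engorged[i] <- runif(1) < p_feed
    if (engorged[i] && heat_in_record) {
      feed_fr <- floor(heat_ch$offset_s[1] * cfg$fps) + 1L
      if (feed_fr <= n) lstate[feed_fr:n] <- cfg$feeding$engorge_state
    }
    ## emission: bouts within each maximal latent run
    r <- rle(lstate)
    lab <- integer(n); cow <- logical(n); pos <- 0L
    for (j in seq_along(r$lengths)) {
      em <- emit_state_run(cfg$states[[r$values[j]]], r$lengths[j], cfg$fps)
      lab[pos + seq_len(r$lengths[j])] <- em$lab
      cow[pos + seq_len(r$lengths[j])] <- em$cow
      pos <- pos + r$lengths[j]
    }
    flags <- cbind(groom = lab == 1L,
                   walk = lab == 2L | (lab == 3L & cow),
                   probe = lab == 3L,
                   fly = lab == 4L)
    track <- NULL
    if (isTRUE(cfg$include_track)) {
      spd_tab <- t(vapply(cfg$states, function(s) s$mean_speed_px_s,
                          numeric(5)))
      spd <- spd_tab[match(lstate, rownames(spd_tab)), ] # n x 5
      step <- spd[cbind(seq_len(n), lab)] / cfg$fps
      heading <- cumsum(rnorm(n, 0, 0.3))
      track <- cbind(x = runif(1, 100, 400) + cumsum(step * cos(heading)),
                     y = runif(1, 100, 400) + cumsum(step * sin(heading)))
    }
    id <- sprintf("sim%03d", i)
    eths[[i]] <- ethogram(id, flags, fps = cfg$fps, track = track)
    latent[[i]] <- lstate
  }
  names(latent) <- vapply(eths, function(e) e$animal_id, "")
  meta <- data.frame(animal_id = names(latent), sex = "female",
                     condition = "sim", engorged = engorged)
  list(cohort = cohort(eths, cfg$stimuli, meta), latent = latent)
}

#' Construct a three-condition additivity scenario
#'
#' Builds a deterministic cohort with conditions `A` (light alone), `B`
#' (heat alone) and `AB` (both), in which each animal's probing response
#' over the first 15 s after stimulus onset is an exact time fraction:
#' `frac_a` under A, `frac_b` under B, and `mode`-dependent under AB --
#' the sum (additive), half the sum (suppressive) or 1.5 times the sum
#' (enhanced).  Used to verify the percent-additivity identities (100%
#' when combined equals the predicted sum, 0% for no response).
#'
#' @param mode `"additive"`, `"suppressive"` or `"enhanced"`.
#' @param config Generator configuration (supplies `n_animals`, `fps`;
#'   stimulus onsets are shared at 300 s).
#' @param frac_a,frac_b Response time fractions for the single-stimulus
#'   conditions (chosen so all fractions are whole numbers of frames).
#' @param window_s Response window after onset (default 15 s).
#' @return A [cohort()] with `condition` metadata `A`, `B`, `AB`.
#' @export
make_additivity_scenario <- function(mode = c("additive", "suppressive",
                                              "enhanced"),
                                     config = default_config(),
                                     frac_a = 0.2, frac_b = 0.2,
                                     window_s = 15) {
  mode <- match.arg(mode)
  factor <- switch(mode, additive = 1, suppressive = 0.5, enhanced = 1.5)
  fps <- config$fps
  onset <- 300
  dur <- max(onset + 2 * window_s + 60, 420)
  n <- as.integer(dur * fps)
  wf <- as.integer(window_s * fps)
  onf <- as.integer(onset * fps)
  mk <- function(id, frac, condition) {
    probe <- rep(FALSE, n)
    k <- as.integer(round(frac * wf))
    if (k > wf) stop("response fraction exceeds 1 in mode ", mode)
    if (k > 0) probe[(onf + 1L):(onf + k)] <- TRUE
    flags <- cbind(groom = FALSE, walk = FALSE, probe = probe, fly = FALSE)
    ethogram(id, flags, fps = fps)
  }
  eths <- list(); cond <- character()
  for (i in seq_len(config$n_animals)) {
    eths <- c(eths, list(mk(sprintf("A_%03d", i), frac_a, "A"),
                         mk(sprintf("B_%03d", i), frac_b, "B"),
                         mk(sprintf("AB_%03d", i), factor * (frac_a + frac_b),
                            "AB")))
    cond <- c(cond, "A", "B", "AB")
  }
  stim <- stimulus_series(list(
    light = data.frame(onset_s = onset, offset_s = onset + 5, magnitude = 1),
    heat = data.frame(onset_s = onset, offset_s = onset + 5, magnitude = 10)))
  meta <- data.frame(animal_id = vapply(eths, function(e) e$animal_id, ""),
                     sex = "female", condition = cond, engorged = NA)
  cohort(eths, stim, meta)
}

#' Analytic response decay curve
#'
#' Noiseless fixture for the half-life statistic: constant `baseline` for
#' `t < 0` and `baseline + (peak - baseline) * 2^(-t / tau_half_s)` for
#' `t >= 0`.  By construction the value at `t = tau_half_s` lies exactly
#' midway between peak and baseline.
#'
#' @param baseline,peak Fractions in `[0, 1]` with `baseline <= peak`.
#' @param tau_half_s Decay half-life in seconds.
#' @param duration_s Post-onset duration covered (default 900 s).
#' @param bin_s Sample spacing in seconds (default 1/30).
#' @param pre_s Pre-onset baseline period covered (default 120 s).
#' @return A [response_curve()].
#' @export
make_decay_curve <- function(baseline, peak, tau_half_s, duration_s = 900,
                             bin_s = 1 / 30, pre_s = 120) {
  if (baseline < 0 || peak > 1 || baseline > peak)
    stop("need 0 <= baseline <= peak <= 1")
  if (tau_half_s <= 0) stop("tau_half_s must be > 0")
  times <- seq(-pre_s, duration_s - bin_s, by = bin_s)
  vals <- ifelse(times < 0, baseline,
                 baseline + (peak - baseline) * 2^(-times / tau_half_s))
  response_curve(times, vals, behavior = "probe", n = NA_integer_,
                 bin_s = bin_s)
}
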