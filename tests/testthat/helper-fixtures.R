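## Shared fixture builders and independent brute-force oracles.  Oracles
## deliberately use naive frame-by-frame loops so they share no code with
## the vectorized implementations they check.

flag_mat <- function(groom = FALSE, walk = FALSE, probe = FALSE,
                     fly = FALSE, n = NULL) {
  if (is.null(n)) n <- max(length(groom), length(walk), length(probe),
                           length(fly))
  cbind(groom = rep_len(groom, n), walk = rep_len(walk, n),
        probe = rep_len(probe, n), fly = rep_len(fly, n))
}

random_ethogram <- function(id = "r1", n = 900, fps = 30, p = 0.25,
                            with_track = TRUE) {
  flags <- cbind(groom = runif(n) < p, walk = runif(n) < p,
                 probe = runif(n) < p, fly = runif(n) < p / 3)
  track <- if (with_track)
    cbind(x = cumsum(rnorm(n)), y = cumsum(rnorm(n)))
  ethogram(id, flags, fps = fps, track = track)
}

tiny_cohort <- function(n_animals = 2, n = 100, fps = 30, seed = 1) {
  set.seed(seed)
  eths <- lapply(seq_len(n_animals), function(i)
    random_ethogram(sprintf("a%02d", i), n = n, fps = fps))
  stim <- stimulus_series(list(
    light = data.frame(onset_s = 1, offset_s = 1.5, magnitude = 1)))
  meta <- data.frame(animal_id = sprintf("a%02d", seq_len(n_animals)),
                     sex = "female", condition = "wt",
                     engorged = seq_len(n_animals) %% 2 == 0)
  cohort(eths, stim, meta)
}

## --- oracles -------------------------------------------------------------

oracle_bout_count <- function(x) {
  x <- as.logical(x)
  cnt <- 0L
  prev <- FALSE
  for (v in x) {
    if (v && !prev) cnt <- cnt + 1L
    prev <- v
  }
  cnt
}

oracle_velocity <- function(track, fps, interval_s = 0.1) {
  m <- as.integer(round(interval_s * fps))
  n <- nrow(track)
  out <- numeric(0)
  i <- 1L
  while (i + m <= n) {
    out <- c(out, sqrt((track[i + m, 1] - track[i, 1])^2 +
                         (track[i + m, 2] - track[i, 2])^2) / interval_s)
    i <- i + m
  }
  out
}

## Exclusive label of one frame by explicit precedence.
oracle_label <- function(fl) {
  if (fl[["fly"]]) "fly"
  else if (fl[["probe"]]) "probe"
  else if (fl[["walk"]]) "walk"
  else if (fl[["groom"]]) "groom"
  else "none"
}

## Full 38-feature frame-scan oracle for one window of an ethogram.
oracle_features <- function(eth, a, b, cutoffs = default_cutoffs(),
                            interval_s = 0.1) {
  idx <- (a + 1L):b
  fl <- eth$flags[idx, , drop = FALSE]
  nw <- length(idx)
  out <- numeric(0)
  for (bh in c("groom", "walk", "probe", "fly"))
    out[paste0("prop_", bh)] <- sum(fl[, bh]) / nw
  out["prop_none"] <- sum(apply(fl, 1, function(r) !any(r))) / nw
  out["prop_probe_walk"] <- sum(fl[, "probe"] & fl[, "walk"]) / nw
  out["prop_probe_not_walk"] <- sum(fl[, "probe"] & !fl[, "walk"]) / nw
  out["prop_walk_not_probe"] <- sum(fl[, "walk"] & !fl[, "probe"]) / nw
  lab <- character(nw)
  for (i in seq_len(nw)) lab[i] <- oracle_label(fl[i, ])
  for (bh in c("groom", "walk", "probe", "fly", "none"))
    out[paste0("bouts_", bh)] <- oracle_bout_count(lab == bh)
  vels <- c(vel_mean = 0, vel_groom = 0, vel_walk = 0, vel_probe = 0,
            vel_fly = 0)
  if (!is.null(eth$track)) {
    v <- oracle_velocity(eth$track, eth$fps, interval_s)
    m <- as.integer(round(interval_s * eth$fps))
    starts <- (seq_along(v) - 1L) * m
    keep <- which(starts >= a & starts < b & !is.na(v))
    if (length(keep)) {
      vels["vel_mean"] <- mean(v[keep])
      for (bh in c("groom", "walk", "probe", "fly")) {
        sel <- keep[lab[starts[keep] - a + 1L] == bh]
        if (length(sel)) vels[paste0("vel_", bh)] <- mean(v[sel])
      }
    }
  }
  cats <- c("fly", "probe", "walk", "groom", "none")
  time_in <- sapply(cats, function(cc) sum(lab == cc) / eth$fps)
  rates <- numeric(0)
  for (src in cats) for (tg in setdiff(cats, src)) {
    cnt <- 0L
    for (i in seq_len(nw - 1))
      if (lab[i] == src && lab[i + 1] == tg) cnt <- cnt + 1L
    rates[paste0("rate_", src, "_", tg)] <-
      if (time_in[src] > 0) cnt / time_in[src] else 0
  }
  for (bh in c("groom", "walk", "probe", "fly")) {
    if (out[paste0("prop_", bh)] < cutoffs[bh]) {
      out[paste0("bouts_", bh)] <- 0
      vels[paste0("vel_", bh)] <- 0
      for (nm in names(rates))
        if (grepl(paste0("^rate_", bh, "_"), nm) ||
              grepl(paste0("_", bh, "$"), nm)) rates[nm] <- 0
    }
  }
  c(out, vels, rates)[feature_names()]
}
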