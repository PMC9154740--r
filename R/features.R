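## The fixed 38-parameter behavioral feature vector, computed per
## (animal, 30 s window).  Families:
##   1-8   raw-flag time proportions: groom, walk, probe, fly, none,
##         probe&walk, probe&!walk, walk&!probe
##   9-13  bout counts of the exclusive categories groom, walk, probe,
##         fly, none (precedence-resolved runs)
##   14-18 velocities (pixels/s): overall mean, mean during groom, walk,
##         probe, fly (velocity samples labeled by their start frame)
##   19-38 outgoing transition rates per second between the five exclusive
##         categories, sources and targets ordered fly, probe, walk,
##         groom, none
## Behaviors whose raw window proportion falls below the minimum-exhibit
## cutoff have their conditional features (bout count, velocity-during,
## transition rates from or to them) set to 0.

feature_names_38 <- local({
  props <- paste0("prop_", c(BEHAVIORS, "none", "probe_walk",
                             "probe_not_walk", "walk_not_probe"))
  bouts <- paste0("bouts_", c(BEHAVIORS, "none"))
  vels <- c("vel_mean", paste0("vel_", BEHAVIORS))
  rates <- unlist(lapply(CATEGORIES, function(a)
    paste0("rate_", a, "_", setdiff(CATEGORIES, a))))
  c(props, bouts, vels, rates)
})

#' Canonical names of the 38 window features
#'
#' @return Character vector of length 38 giving the fixed feature order:
#'   8 proportions, 5 bout counts, 5 velocities, 20 transition rates.
#' @export
feature_names <- function() feature_names_38

#' Default minimum-exhibit cutoffs
#'
#' Window-proportion thresholds below which a behavior is considered not
#' exhibited in that window: 0.04 for flight, 0.2 for walking or probing,
#' 0.3 for grooming.
#'
#' @return Named numeric vector over `groom`, `walk`, `probe`, `fly`.
#' @export
default_cutoffs <- function() c(groom = 0.3, walk = 0.2, probe = 0.2,
                                fly = 0.04)

#' Sliding windows over an ethogram
#'
#' Frame spans `[k * step, k * step + length)` for `k = 0, 1, ...`; the
#' default splits each track into 30 s intervals at 10 s step size.  A
#' final partial window is dropped.
#'
#' @param eth An `ethogram` (or anything with `n_frames`).
#' @param length_s,step_s Window length and step in seconds.
#' @return Data frame with columns `start_frame`, `end_frame`, `start_s`.
#' @export
make_windows <- function(eth, length_s = 30, step_s = 10) {
  stopifnot(length_s > 0, step_s > 0, step_s <= length_s)
  n <- n_frames(eth)
  L <- as.integer(round(length_s * eth$fps))
  s <- as.integer(round(step_s * eth$fps))
  if (n < L) stop("record shorter than one window")
  k <- (n - L) %/% s
  starts <- (0:k) * s
  data.frame(start_frame = starts, end_frame = starts + L,
             start_s = starts / eth$fps)
}

#' Outgoing behavior transition rates
#'
#' Rate per second of transitions from each exclusive category to each
#' other category: the number of consecutive-frame label changes a -> b
#' within the span, divided by the time spent in a (seconds); 0 when no
#' time is spent in a.
#'
#' @param labels Factor of exclusive labels (levels
#'   `fly, probe, walk, groom, none`), e.g. from [resolve_precedence()].
#' @param fps Frames per second.
#' @return Named numeric vector of the 20 ordered rates.
#' @export
transition_rates <- function(labels, fps) {
  labels <- factor(labels, levels = CATEGORIES)
  n <- length(labels)
  counts <- matrix(0, 5, 5, dimnames = list(CATEGORIES, CATEGORIES))
  if (n > 1) {
    a <- labels[-n]; b <- labels[-1]
    chg <- which(a != b)
    if (length(chg)) {
      tab <- table(a[chg], b[chg])
      counts[rownames(tab), colnames(tab)] <- tab
    }
  }
  time_in <- as.numeric(table(labels)) / fps
  names(time_in) <- CATEGORIES
  out <- numeric(0)
  for (src in CATEGORIES) {
    tg <- setdiff(CATEGORIES, src)
    r <- if (time_in[src] > 0) counts[src, tg] / time_in[src] else
      rep(0, 4)
    names(r) <- paste0("rate_", src, "_", tg)
    out <- c(out, r)
  }
  out
}

#' Extract the 38-feature vector for one window
#'
#' @param eth An `ethogram`.
#' @param span Either a row of [make_windows()] output or
#'   `c(start_frame, end_frame)` (0-based, half-open).
#' @param cutoffs Minimum-exhibit thresholds ([default_cutoffs()]).
#' @param velocity Optional precomputed [compute_velocity()] series for
#'   the whole ethogram (avoids recomputation across windows); computed
#'   on demand when the ethogram has a track, velocity features are 0
#'   when it has none.
#' @param interval_s Velocity sampling interval (default 0.1 s).
#' @return Named numeric vector of length 38 in [feature_names()] order.
#' @export
extract_features <- function(eth, span, cutoffs = default_cutoffs(),
                             velocity = NULL, interval_s = 0.1) {
  if (is.data.frame(span)) span <- c(span$start_frame[1], span$end_frame[1])
  a <- as.integer(span[1]); b <- as.integer(span[2])
  if (a < 0 || b > n_frames(eth) || b <= a) stop("invalid span")
  idx <- (a + 1L):b
  fl <- eth$flags[idx, , drop = FALSE]
  nw <- length(idx)
  anyflag <- fl[, 1] | fl[, 2] | fl[, 3] | fl[, 4]
  props <- c(colMeans(fl)[BEHAVIORS], none = mean(!anyflag),
             probe_walk = mean(fl[, "probe"] & fl[, "walk"]),
             probe_not_walk = mean(fl[, "probe"] & !fl[, "walk"]),
             walk_not_probe = mean(fl[, "walk"] & !fl[, "probe"]))
  names(props) <- paste0("prop_", names(props))
  lab <- resolve_precedence(fl)
  bouts <- vapply(c(BEHAVIORS, "none"), function(bh)
    nrow(find_bouts(lab == bh)), 0)
  names(bouts) <- paste0("bouts_", names(bouts))
  ## velocity samples whose start frame lies in the span
  vels <- c(vel_mean = 0, vel_groom = 0, vel_walk = 0, vel_probe = 0,
            vel_fly = 0)
  if (is.null(velocity) && !is.null(eth$track))
    velocity <- compute_velocity(eth, interval_s)
  if (!is.null(velocity) && length(velocity)) {
    m <- as.integer(round(interval_s * eth$fps))
    vstart <- (seq_along(velocity) - 1L) * m      # 0-based start frames
    vin <- which(vstart >= a & vstart < b)
    if (length(vin)) {
      v <- velocity[vin]
      vlab <- lab[vstart[vin] - a + 1L]
      vels["vel_mean"] <- mean(v, na.rm = TRUE)
      for (bh in BEHAVIORS) {
        sel <- vlab == bh & !is.na(v)
        if (any(sel)) vels[paste0("vel_", bh)] <- mean(v[sel])
      }
      if (is.nan(vels["vel_mean"])) vels["vel_mean"] <- 0
    }
  }
  rates <- transition_rates(lab, eth$fps)
  ## minimum-exhibit cutoffs: zero conditional features of behaviors
  ## whose raw proportion is below threshold
  for (bh in BEHAVIORS) {
    if (props[paste0("prop_", bh)] < cutoffs[bh]) {
      bouts[paste0("bouts_", bh)] <- 0
      vels[paste0("vel_", bh)] <- 0
      hit <- grepl(paste0("^rate_", bh, "_"), names(rates)) |
        grepl(paste0("_", bh, "$"), names(rates))
      rates[hit] <- 0
    }
  }
  out <- c(props, bouts, vels, rates)
  stopifnot(identical(names(out), feature_names_38))
  out
}

#' Window-feature table for a whole cohort
#'
#' Applies [make_windows()] and [extract_features()] to every animal.
#'
#' @param x A `cohort`.
#' @param length_s,step_s Window length and step in seconds (defaults 30
#'   and 10).
#' @param cutoffs Minimum-exhibit thresholds.
#' @return Data frame with `animal_id`, `start_s`, and the 38 feature
#'   columns in canonical order.
#' @export
window_features <- function(x, length_s = 30, step_s = 10,
                            cutoffs = default_cutoffs()) {
  rows <- lapply(x$ethograms, function(eth) {
    w <- make_windows(eth, length_s, step_s)
    vel <- if (!is.null(eth$track)) compute_velocity(eth) else NULL
    feats <- t(vapply(seq_len(nrow(w)), function(i)
      extract_features(eth, c(w$start_frame[i], w$end_frame[i]), cutoffs,
                       velocity = vel),
      numeric(38)))
    data.frame(animal_id = eth$animal_id, start_s = w$start_s, feats,
               check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
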