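#' Construct a population response curve
#'
#' A response curve is a uniformly sampled time series, relative to a
#' stimulus onset at `t = 0`, of the fraction of animals exhibiting a
#' behavior (or the mean per-animal time fraction).
#'
#' @param times_s Strictly increasing uniform sample grid (bin start
#'   times, seconds relative to onset).
#' @param values Fractions in `[0, 1]`, same length as `times_s`.
#' @param behavior Behavior name the curve describes.
#' @param n Number of animals contributing.
#' @param bin_s Bin width in seconds.
#' @return An object of class `"response_curve"`.
#' @export
response_curve <- function(times_s, values, behavior = "probe",
                           n = NA_integer_, bin_s = NULL) {
  if (length(times_s) != length(values)) stop("times and values differ")
  d <- diff(times_s)
  if (length(d) && (any(d <= 0) || diff(range(d)) > 1e-8 * max(d)))
    stop("times must be a strictly increasing uniform grid")
  if (any(values < -1e-9 | values > 1 + 1e-9, na.rm = TRUE))
    stop("values must lie in [0, 1]")
  if (is.null(bin_s)) bin_s <- if (length(d)) d[1] else NA_real_
  structure(list(times_s = as.numeric(times_s), values = as.numeric(values),
                 behavior = behavior, n = n, bin_s = bin_s),
            class = "response_curve")
}

#' @export
print.response_curve <- function(x, ...) {
  cat(sprintf("<response_curve> %s: %d bins of %.3g s, t in [%g, %g], n = %s\n",
              x$behavior, length(x$values), x$bin_s, min(x$times_s),
              max(x$times_s), x$n))
  invisible(x)
}

#' Fraction of animals exhibiting a behavior over time
#'
#' At each time bin, the fraction of animals whose raw flag for the
#' behavior is on during at least one frame of the bin (the "% individuals
#' exhibiting" statistic); with `per_animal_time = TRUE`, the mean over
#' animals of the per-animal fraction of flagged frames in the bin.
#'
#' @param x A `cohort`, normally after [align_to_stimulus()].
#' @param behavior One of `groom`, `walk`, `probe`, `fly`.
#' @param bin_s Bin width in seconds; must be a multiple of `1/fps`
#'   (default one frame).
#' @param per_animal_time Use per-animal time fractions instead of the
#'   any-frame indicator.
#' @return A [response_curve()] (times are bin start times; bins tile the
#'   recording from frame 0).
#' @export
fraction_exhibiting <- function(x, behavior = "probe", bin_s = NULL,
                                per_animal_time = FALSE) {
  if (!length(x$ethograms)) stop("empty cohort")
  behavior <- match.arg(behavior, BEHAVIORS)
  fps <- cohort_fps(x)
  if (is.null(bin_s)) bin_s <- 1 / fps
  m <- bin_s * fps
  if (abs(m - round(m)) > 1e-9 || m < 1)
    stop("bin_s must be a positive multiple of 1/fps")
  m <- as.integer(round(m))
  nf <- min(vapply(x$ethograms, n_frames, 0L))
  nb <- nf %/% m
  per <- vapply(x$ethograms, function(e) {
    f <- e$flags[seq_len(nb * m), behavior]
    dim(f) <- c(m, nb)
    if (per_animal_time) colMeans(f) else as.numeric(colSums(f) > 0)
  }, numeric(nb))
  origin <- x$ethograms[[1]]$origin_s
  response_curve(times_s = (seq_len(nb) - 1L) * m / fps - origin,
                 values = rowMeans(matrix(per, nrow = nb)),
                 behavior = behavior, n = length(x$ethograms), bin_s = bin_s)
}

#' Sliding-window mean of a response curve
#'
#' For every sample time `t >= 0`, the mean of the curve over
#' `[t, t + window_s)`; windows truncated by the end of the record are
#' dropped.
#'
#' @param curve A [response_curve()] covering `t >= 0`.
#' @param window_s Window length in seconds (default 15).
#' @return A [response_curve()] on the post-onset grid.
#' @export
sliding_window_response <- function(curve, window_s = 15) {
  keep <- curve$times_s >= -1e-9
  if (!any(keep)) stop("curve does not cover t >= 0")
  v <- curve$values[keep]
  t <- curve$times_s[keep]
  w <- as.integer(round(window_s / curve$bin_s))
  if (w < 1 || w > length(v)) stop("window longer than record")
  cs <- cumsum(c(0, v))
  out <- (cs[(w + 1):length(cs)] - cs[1:(length(cs) - w)]) / w
  response_curve(t[seq_along(out)], out, behavior = curve$behavior,
                 n = curve$n, bin_s = curve$bin_s)
}

#' Nonparametric response decay half-life
#'
#' The half-life of a stimulus-evoked response: baseline is the mean of
#' the raw curve over the `baseline_window_s` seconds before onset; the
#' maximum response is the largest value of the sliding-window mean
#' ([sliding_window_response()]) after onset (earliest window on ties);
#' and the half-life is the first window at or after the maximum in which
#' the response has fallen to or below halfway between maximum and
#' baseline.  The statistic is reported in minutes.  The search starts at
#' the maximum (not at onset) because the rising phase also crosses the
#' halfway level.
#'
#' @param curve A [response_curve()] covering `[-baseline_window_s, 0)`
#'   and `t >= 0`.
#' @param baseline_window_s Pre-onset baseline period (default 120 s).
#' @param window_s Sliding-window length (default 15 s).
#' @return A list of class `"half_life_result"` with elements `baseline`,
#'   `max_response`, `argmax_time_s`, `t_half_min`, `censored` (logical),
#'   `reason` (`NA`, `"no response"` or `"right-censored"`).
#' @export
half_life <- function(curve, baseline_window_s = 120, window_s = 15) {
  pre <- curve$times_s >= -baseline_window_s - 1e-9 & curve$times_s < -1e-9
  if (!any(pre)) stop("curve does not cover the pre-onset baseline window")
  baseline <- mean(curve$values[pre])
  win <- sliding_window_response(curve, window_s)
  res <- list(baseline = baseline, max_response = max(win$values),
              argmax_time_s = NA_real_, t_half_min = NA_real_,
              censored = TRUE, reason = NA_character_)
  class(res) <- "half_life_result"
  if (res$max_response <= baseline + 1e-12) {
    res$reason <- "no response"
    return(res)
  }
  imax <- which.max(win$values)              # earliest on ties
  res$argmax_time_s <- win$times_s[imax]
  halfway <- baseline + (res$max_response - baseline) / 2
  below <- which(win$values[imax:length(win$values)] <= halfway + 1e-12)
  if (!length(below)) {
    res$reason <- "right-censored"
    return(res)
  }
  res$t_half_min <- win$times_s[imax + below[1] - 1L] / 60
  res$censored <- FALSE
  res
}

#' @export
print.half_life_result <- function(x, ...) {
  if (x$censored)
    cat(sprintf("<half_life> censored (%s); baseline %.3f, max %.3f\n",
                x$reason, x$baseline, x$max_response))
  else
    cat(sprintf("<half_life> t1/2 = %.2f min (baseline %.3f, max %.3f at %g s)\n",
                x$t_half_min, x$baseline, x$max_response, x$argmax_time_s))
  invisible(x)
}

#' Predicted additive response
#'
#' The elementwise (or scalar) sum of the cohort-average responses to two
#' stimuli presented individually.
#'
#' @param resp_a,resp_b Scalars or [response_curve()]s on matching grids.
#' @return Same shape as the inputs.
#' @export
predicted_additive <- function(resp_a, resp_b) {
  if (inherits(resp_a, "response_curve") && inherits(resp_b, "response_curve")) {
    if (length(resp_a$times_s) != length(resp_b$times_s) ||
        max(abs(resp_a$times_s - resp_b$times_s)) > 1e-9)
      stop("response grids do not match")
    out <- resp_a
    out$values <- resp_a$values + resp_b$values  # may exceed 1 by design
    out$n <- NA_integer_
    return(out)
  }
  if (is.numeric(resp_a) && is.numeric(resp_b)) return(resp_a + resp_b)
  stop("inputs must both be scalars or both response curves")
}

#' Percent additivity of a multimodal response
#'
#' For each animal tested with the combined stimulus, its response divided
#' by the predicted additive response (sum of the mean responses to the
#' individual stimuli), times 100%: 0% is no response, 100% exactly
#' additive, above 100% super-additive.
#'
#' @param combined Per-animal response scalars under the combined stimulus.
#' @param predicted Predicted additive response (positive scalar).
#' @return List with `per_animal` (percent per animal), `median_pct`, `n`.
#' @export
percent_additivity <- function(combined, predicted) {
  if (!is.numeric(predicted) || length(predicted) != 1)
    stop("predicted must be a scalar")
  if (is.na(predicted) || predicted <= 0) {
    warning("predicted additive response is not positive; additivity undefined")
    return(list(per_animal = rep(NA_real_, length(combined)),
                median_pct = NA_real_, n = 0L))
  }
  pct <- 100 * combined / predicted
  list(per_animal = pct, median_pct = median(pct, na.rm = TRUE),
       n = sum(!is.na(pct)))
}

#' Per-animal mean response in a time window
#'
#' Mean of the raw behavior flag over a time window relative to the
#' current alignment origin, for every animal in the cohort.
#'
#' @param x A `cohort` (aligned so the window is meaningful).
#' @param behavior Behavior name.
#' @param window `c(t0, t1)` in seconds, half-open `[t0, t1)`.
#' @return Named numeric vector, one fraction per animal.
#' @export
animal_response <- function(x, behavior = "probe", window = c(0, 15)) {
  behavior <- match.arg(behavior, BEHAVIORS)
  vapply(x$ethograms, function(e) {
    tt <- frame_times(e)
    sel <- tt >= window[1] - 1e-9 & tt < window[2] - 1e-9
    if (!any(sel)) stop("empty response window for animal ", e$animal_id)
    mean(e$flags[sel, behavior])
  }, 0)
}

#' Cohort-level additivity analysis
#'
#' Convenience wrapper for a three-condition cohort (conditions `A`, `B`,
#' `AB` in the metadata, stimuli sharing one onset): computes the mean
#' response to each individual stimulus over the response window, their
#' sum as the predicted additive response, and [percent_additivity()] of
#' each combined-condition animal.
#'
#' @param x A three-condition `cohort` (e.g. [make_additivity_scenario()]).
#' @param behavior Behavior name (default `probe`).
#' @param window Response window in seconds relative to onset (default the
#'   first 15 s).
#' @param channel Channel whose first pulse defines `t = 0`.
#' @return List with `predicted`, `per_animal`, `median_pct`, `n`.
#' @export
cohort_additivity <- function(x, behavior = "probe", window = c(0, 15),
                              channel = "light") {
  x <- align_to_stimulus(x, channel, 1L)
  cond <- x$meta$condition
  sub <- function(cc) {
    keep <- which(cond == cc)
    if (!length(keep)) stop("cohort has no condition ", cc)
    cohort(x$ethograms[keep], x$stimuli, x$meta[keep, ])
  }
  mean_a <- mean(animal_response(sub("A"), behavior, window))
  mean_b <- mean(animal_response(sub("B"), behavior, window))
  combined <- animal_response(sub("AB"), behavior, window)
  pred <- predicted_additive(mean_a, mean_b)
  out <- percent_additivity(combined, pred)
  out$predicted <- pred
  out
}

#' Smooth a time-resolved additivity series
#'
#' Centered moving average over a 4.5 s span around each 500 ms timepoint
#' (9 bins); at the edges only the available bins are averaged.
#'
#' @param series Numeric vector sampled on a uniform 500 ms grid.
#' @param span_bins Number of bins in the smoothing span (odd; default 9).
#' @return Smoothed numeric vector of the same length.
#' @export
smooth_additivity <- function(series, span_bins = 9L) {
  if (span_bins %% 2 == 0) stop("span_bins must be odd")
  h <- span_bins %/% 2
  n <- length(series)
  cs <- cumsum(c(0, series))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
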