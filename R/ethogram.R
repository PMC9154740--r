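#' Construct an ethogram for one animal
#'
#' An ethogram holds the per-frame boolean behavior flags produced by frame
#' classifiers (groom, walk, probe, fly) for a single animal, at a fixed
#' frame rate, together with an optional x-y centroid track.  Flags are raw
#' (non-exclusive): probing and walking genuinely co-occur; use
#' [resolve_precedence()] to obtain a single exclusive category per frame.
#'
#' Frames are 0-based and all frame spans in this package are half-open
#' `[start, end)`.  The time of frame `k` is `k / fps - origin_s` seconds,
#' where `origin_s` is the current alignment origin (0 for an unaligned
#' recording; see [align_to_stimulus()]).
#'
#' @param animal_id Character scalar identifying the animal.
#' @param flags Logical (or 0/1) matrix with one row per frame and columns
#'   `groom`, `walk`, `probe`, `fly`.
#' @param fps Frame rate in frames per second (default 30).
#' @param track Optional numeric matrix of per-frame centroid positions with
#'   columns `x`, `y`, in pixels; `NA` rows mark tracking gaps.
#' @param origin_s Time origin in seconds (frame 0 sits at `-origin_s`).
#' @return An object of class `"ethogram"`.
#' @export
ethogram <- function(animal_id, flags, fps = 30, track = NULL, origin_s = 0) {
  flags <- as.matrix(flags)
  if (is.null(colnames(flags))) colnames(flags) <- BEHAVIORS
  if (!setequal(colnames(flags), BEHAVIORS))
    stop("flags must have columns ", paste(BEHAVIORS, collapse = ", "))
  flags <- flags[, BEHAVIORS, drop = FALSE]
  storage.mode(flags) <- "logical"
  if (anyNA(flags)) stop("flags must not contain NA (animal ", animal_id, ")")
  if (!is.numeric(fps) || length(fps) != 1 || fps <= 0)
    stop("fps must be a positive scalar")
  if (!is.null(track)) {
    track <- as.matrix(track)
    if (ncol(track) != 2) stop("track must have two columns (x, y)")
    colnames(track) <- c("x", "y")
    storage.mode(track) <- "double"
    if (nrow(track) != nrow(flags))
      stop("track length (", nrow(track), ") does not match flags (",
           nrow(flags), ") for animal ", animal_id)
  }
  structure(
    list(animal_id = as.character(animal_id), fps = as.numeric(fps),
         flags = flags, track = track, origin_s = as.numeric(origin_s)),
    class = "ethogram")
}

#' @export
print.ethogram <- function(x, ...) {
  cat(sprintf("<ethogram> animal %s: %d frames @ %g fps (%.1f s)%s\n",
              x$animal_id, n_frames(x), x$fps, n_frames(x) / x$fps,
              if (is.null(x$track)) ", no track" else ", with track"))
  invisible(x)
}

#' Number of frames in an ethogram
#' @param x An `ethogram`.
#' @return Integer frame count.
#' @export
n_frames <- function(x) nrow(x$flags)

#' Construct a stimulus series
#'
#' A stimulus series holds named stimulus channels (e.g. `light`, `heat`),
#' each a set of non-overlapping pulses given as onset/offset times in
#' seconds with an arbitrary-unit magnitude.
#'
#' @param channels Named list; each element a data frame (or list) with
#'   columns `onset_s`, `offset_s`, `magnitude`.
#' @return An object of class `"stimulus_series"`.
#' @export
stimulus_series <- function(channels = list()) {
  channels <- lapply(channels, function(ch) {
    ch <- as.data.frame(ch)
    if (!all(c("onset_s", "offset_s", "magnitude") %in% names(ch)))
      stop("each channel needs onset_s, offset_s, magnitude")
    ch <- ch[order(ch$onset_s), c("onset_s", "offset_s", "magnitude")]
    if (nrow(ch)) {
      if (any(ch$onset_s < 0) || any(ch$offset_s <= ch$onset_s))
        stop("pulses need 0 <= onset < offset")
      if (nrow(ch) > 1 && any(ch$onset_s[-1] < ch$offset_s[-nrow(ch)]))
        stop("pulses within a channel must not overlap")
    }
    rownames(ch) <- NULL
    ch
  })
  structure(list(channels = channels), class = "stimulus_series")
}

#' @export
print.stimulus_series <- function(x, ...) {
  cat("<stimulus_series>", length(x$channels), "channel(s)\n")
  for (nm in names(x$channels))
    cat(sprintf("  %s: %d pulse(s)\n", nm, nrow(x$channels[[nm]])))
  invisible(x)
}

#' Construct a cohort dataset
#'
#' The unit every pipeline stage consumes: a list of ethograms sharing one
#' frame rate and one stimulus timeline, plus per-animal metadata (sex,
#' condition, engorged outcome).
#'
#' @param ethograms List of [ethogram()] objects.
#' @param stimuli A [stimulus_series()] shared by the cohort.
#' @param meta Data frame with columns `animal_id`, `sex`, `condition`,
#'   `engorged` (logical, `NA` when unknown); one row per ethogram.
#' @return An object of class `"cohort"`.
#' @export
cohort <- function(ethograms, stimuli = stimulus_series(), meta = NULL) {
  ids <- vapply(ethograms, function(e) e$animal_id, "")
  if (anyDuplicated(ids)) stop("duplicate animal_id in cohort")
  names(ethograms) <- ids
  if (is.null(meta)) {
    meta <- data.frame(animal_id = ids,
                       sex = rep(NA_character_, length(ids)),
                       condition = rep(NA_character_, length(ids)),
                       engorged = rep(NA, length(ids)),
                       stringsAsFactors = FALSE)
  }
  meta <- as.data.frame(meta)
  need <- c("animal_id", "sex", "condition", "engorged")
  for (nm in setdiff(need, names(meta))) meta[[nm]] <- NA
  meta <- meta[, need]
  meta$engorged <- as.logical(meta$engorged)
  if (!setequal(meta$animal_id, ids) || nrow(meta) != length(ids))
    stop("meta must have exactly one record per ethogram")
  meta <- meta[match(ids, meta$animal_id), ]
  rownames(meta) <- NULL
  fps <- unique(vapply(ethograms, function(e) e$fps, 0))
  if (length(ethograms) && length(fps) != 1)
    stop("all ethograms in a cohort must share one fps")
  structure(list(ethograms = ethograms, stimuli = stimuli, meta = meta),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d animal(s), %d stimulus channel(s)\n",
              length(x$ethograms), length(x$stimuli$channels)))
  invisible(x)
}

#' Cohort frame rate
#' @param x A `cohort`.
#' @return Frames per second shared by all ethograms.
#' @export
cohort_fps <- function(x) {
  if (!length(x$ethograms)) stop("empty cohort has no fps")
  x$ethograms[[1]]$fps
}

#' Resolve co-occurring behavior flags to one exclusive category
#'
#' Frame classifiers occasionally fire for several behaviors on the same
#' frame (and probing while walking is biologically real).  Where a single
#' category per frame is needed (transitions, state ethograms) the standard
#' precedence is flying > probing > walking > grooming > no behavior.
#'
#' @param flags Logical matrix with columns `groom`, `walk`, `probe`, `fly`
#'   (one row per frame), or a character vector of flag names for one frame.
#' @return Factor of exclusive labels with levels
#'   `fly, probe, walk, groom, none`, one per frame.
#' @export
resolve_precedence <- function(flags) {
  if (is.character(flags)) {
    bad <- setdiff(flags, BEHAVIORS)
    if (length(bad)) stop("unknown behavior flag: ", paste(bad, collapse = ", "))
    m <- matrix(BEHAVIORS %in% flags, nrow = 1,
                dimnames = list(NULL, BEHAVIORS))
    return(resolve_precedence(m))
  }
  flags <- flags[, BEHAVIORS, drop = FALSE]
  ## highest-precedence TRUE column, else none
  idx <- rep.int(5L, nrow(flags))
  for (i in rev(seq_along(PRECEDENCE)))   # groom first so fly overwrites last
    idx[flags[, PRECEDENCE[i]]] <- i
  factor(CATEGORIES[idx], levels = CATEGORIES)
}

#' Find behavior bouts in a binary series
#'
#' A bout is a maximal run of consecutive `TRUE` frames.  Spans are
#' half-open 0-based frame intervals `[start, end)`, sorted by start.
#'
#' @param x Logical vector (per-frame flag for one behavior).
#' @return Data frame with columns `start_frame`, `end_frame`, `length`.
#' @export
find_bouts <- function(x) {
  x <- as.logical(x)
  x[is.na(x)] <- FALSE
  if (!length(x) || !any(x))
    return(data.frame(start_frame = integer(), end_frame = integer(),
                      length = integer()))
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  data.frame(start_frame = starts[keep], end_frame = ends[keep],
             length = r$lengths[keep])
}

#' Compute centroid speed at fixed intervals
#'
#' Speed is the Euclidean displacement of the centroid over consecutive
#' `interval_s` intervals divided by `interval_s`, following the convention
#' of sampling the tracked x-y position every 100 ms (three frames at
#' 30 fps).  Sample `k` (1-based) spans frames `[(k-1)m, km]` where
#' `m = interval_s * fps`; samples whose endpoints fall in tracking gaps
#' are `NA` and are excluded from downstream averages.
#'
#' @param eth An [ethogram()] with a track.
#' @param interval_s Sampling interval in seconds; must be a positive
#'   multiple of `1/fps` (default 0.1).
#' @return Numeric vector of speeds in pixels/s, one per complete interval
#'   (`floor((frames - 1) / m)` samples).
#' @export
compute_velocity <- function(eth, interval_s = 0.1) {
  if (is.null(eth$track)) stop("no track for animal ", eth$animal_id)
  m <- interval_s * eth$fps
  if (interval_s <= 0 || abs(m - round(m)) > 1e-9)
    stop("interval_s must be a positive multiple of 1/fps")
  m <- as.integer(round(m))
  n <- n_frames(eth)
  k <- (n - 1L) %/% m
  if (k < 1L) return(numeric(0))
  at <- seq(0L, k * m, by = m) + 1L   # 1-based row indices
  dx <- diff(eth$track[at, 1L])
  dy <- diff(eth$track[at, 2L])
  sqrt(dx^2 + dy^2) / interval_s
}

#' Align a cohort to a stimulus pulse
#'
#' Re-indexes time so that `t = 0` is the onset of the chosen pulse; all
#' downstream response curves use times relative to this origin.  The
#' operation is invertible: aligning back to origin 0 restores the original
#' time base (no frames are dropped).
#'
#' @param x A `cohort`.
#' @param channel Stimulus channel name.
#' @param pulse 1-based pulse index within the channel.
#' @return The cohort with every ethogram's `origin_s` set to the pulse
#'   onset, and the chosen origin recorded in `attr(x, "aligned_to")`.
#' @export
align_to_stimulus <- function(x, channel, pulse = 1L) {
  ch <- x$stimuli$channels[[channel]]
  if (is.null(ch)) stop("unknown stimulus channel: ", channel)
  if (pulse < 1 || pulse > nrow(ch))
    stop("channel ", channel, " has no pulse ", pulse)
  onset <- ch$onset_s[pulse]
  x$ethograms <- lapply(x$ethograms, function(e) { e$origin_s <- onset; e })
  attr(x, "aligned_to") <- list(channel = channel, pulse = pulse,
                                onset_s = onset)
  x
}

#' Per-frame times of an ethogram
#' @param eth An `ethogram`.
#' @return Numeric vector, time in seconds of each frame relative to the
#'   current origin.
#' @export
frame_times <- function(eth) {
  (seq_len(n_frames(eth)) - 1L) / eth$fps - eth$origin_s
}
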