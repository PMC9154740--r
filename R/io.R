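## Cohort serialization.
##
## Canonical on-disk dialect (format "csv_dir"): one CSV per animal named
## <animal_id>.csv with header frame,time_s,groom,walk,probe,fly,x,y (flags
## 0/1; x,y empty when no track), plus meta.csv
## (animal_id,sex,condition,engorged; engorged empty when unknown) and
## stimuli.json (channels -> pulse list with onset_s, offset_s, magnitude).
## Format "json" packs the same content into a single JSON file.
## write_cohort() output is canonical: read_cohort() followed by
## write_cohort() reproduces it byte for byte.

ETHO_HEADER <- c("frame", "time_s", "groom", "walk", "probe", "fly", "x", "y")

fmt_num <- function(x) {
  out <- sprintf("%.6f", x)
  out[is.na(x)] <- ""
  out
}

#' Write a cohort to disk
#'
#' @param x A [cohort()].
#' @param path Directory (format `csv_dir`) or file path (format `json`).
#' @param format `"csv_dir"` (one CSV per animal plus `meta.csv` and
#'   `stimuli.json`) or `"json"` (single file).
#' @return `path`, invisibly.
#' @seealso [read_cohort()] for the dialect.
#' @export
write_cohort <- function(x, path, format = c("csv_dir", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "cohort"))
  if (format == "json") {
    jsonlite::write_json(cohort_to_list(x), path, auto_unbox = TRUE,
                         digits = 8, pretty = FALSE, na = "null")
    return(invisible(path))
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (eth in x$ethograms) {
    n <- n_frames(eth)
    frames <- seq_len(n) - 1L
    if (is.null(eth$track)) {
      xs <- ys <- rep("", n)
    } else {
      xs <- fmt_num(eth$track[, 1]); ys <- fmt_num(eth$track[, 2])
    }
    lines <- paste(frames, fmt_num(frames / eth$fps),
                   eth$flags[, "groom"] + 0L, eth$flags[, "walk"] + 0L,
                   eth$flags[, "probe"] + 0L, eth$flags[, "fly"] + 0L,
                   xs, ys, sep = ",")
    writeLines(c(paste(ETHO_HEADER, collapse = ","), lines),
               file.path(path, paste0(eth$animal_id, ".csv")))
  }
  meta <- x$meta
  eng <- ifelse(is.na(meta$engorged), "", ifelse(meta$engorged, "1", "0"))
  chr <- function(v) ifelse(is.na(v), "", as.character(v))
  writeLines(c("animal_id,sex,condition,engorged",
               paste(meta$animal_id, chr(meta$sex), chr(meta$condition),
                     eng, sep = ",")),
             file.path(path, "meta.csv"))
  jsonlite::write_json(list(channels = x$stimuli$channels),
                       file.path(path, "stimuli.json"),
                       auto_unbox = TRUE, digits = 8, dataframe = "rows")
  invisible(path)
}

cohort_to_list <- function(x) {
  list(
    fps = if (length(x$ethograms)) cohort_fps(x) else 30,
    stimuli = list(channels = x$stimuli$channels),
    animals = lapply(seq_along(x$ethograms), function(i) {
      eth <- x$ethograms[[i]]
      m <- x$meta[i, ]
      out <- list(animal_id = eth$animal_id, sex = m$sex,
                  condition = m$condition, engorged = m$engorged,
                  groom = as.integer(eth$flags[, "groom"]),
                  walk = as.integer(eth$flags[, "walk"]),
                  probe = as.integer(eth$flags[, "probe"]),
                  fly = as.integer(eth$flags[, "fly"]))
      if (!is.null(eth$track)) {
        out$x <- eth$track[, 1]; out$y <- eth$track[, 2]
      }
      out
    }))
}

#' Read a cohort from disk
#'
#' Reads the canonical cohort layout written by [write_cohort()] and
#' validates every container invariant (matching frame counts, shared fps,
#' one metadata record per animal, well-formed pulses).  Malformed input
#' raises an error naming the offending file.
#'
#' @param path Directory (`csv_dir`) or file (`json`).
#' @param format `"csv_dir"` or `"json"`.
#' @return A validated [cohort()].
#' @export
read_cohort <- function(path, format = c("csv_dir", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    stim <- stimulus_series(lapply(obj$stimuli$channels, as.data.frame))
    ans <- obj$animals
    eths <- list(); meta <- NULL
    for (i in seq_along(ans$animal_id)) {
      flags <- cbind(groom = ans$groom[[i]], walk = ans$walk[[i]],
                     probe = ans$probe[[i]], fly = ans$fly[[i]])
      track <- if (!is.null(ans$x) && !is.null(ans$x[[i]]))
        cbind(x = ans$x[[i]], y = ans$y[[i]])
      eths[[i]] <- ethogram(ans$animal_id[i], flags, fps = obj$fps,
                            track = track)
    }
    meta <- data.frame(animal_id = ans$animal_id, sex = ans$sex,
                       condition = ans$condition, engorged = ans$engorged)
    return(cohort(eths, stim, meta))
  }
  meta_file <- file.path(path, "meta.csv")
  if (!file.exists(meta_file)) stop("missing ", meta_file)
  meta <- read.csv(meta_file, colClasses = "character")
  if (!identical(names(meta), c("animal_id", "sex", "condition", "engorged")))
    stop("malformed header in ", meta_file)
  meta$engorged <- ifelse(meta$engorged == "", NA, meta$engorged == "1")
  meta$sex[meta$sex == ""] <- NA
  meta$condition[meta$condition == ""] <- NA
  stim_file <- file.path(path, "stimuli.json")
  stim <- if (file.exists(stim_file)) {
    obj <- jsonlite::read_json(stim_file, simplifyVector = TRUE)
    stimulus_series(lapply(obj$channels, as.data.frame))
  } else stimulus_series()
  eths <- lapply(meta$animal_id, function(id) {
    f <- file.path(path, paste0(id, ".csv"))
    if (!file.exists(f)) stop("missing ethogram file ", f)
    d <- read.csv(f)
    if (!identical(names(d), ETHO_HEADER))
      stop("malformed header in ", f, " (line 1)")
    bad <- which(!(d$groom %in% 0:1 & d$walk %in% 0:1 &
                   d$probe %in% 0:1 & d$fly %in% 0:1))
    if (length(bad))
      stop("non-binary behavior flag in ", f, " (line ", bad[1] + 1L, ")")
    n <- nrow(d)
    fps <- if (n > 1) round((n - 1) / d$time_s[n], 6) else 30
    track <- NULL
    if (any(!is.na(d$x) | !is.na(d$y))) track <- cbind(x = d$x, y = d$y)
    ethogram(id, d[, BEHAVIORS], fps = fps, track = track)
  })
  cohort(eths, stim, meta)
}

#' Validate a cohort directory or object
#'
#' Checks every invariant the pipeline relies on: readable canonical files,
#' equal flag/track frame counts, shared fps, sorted non-overlapping pulses,
#' one meta record per animal.  Problems are reported as structured
#' `WARN`/`ERROR` lines on standard error.
#'
#' @param x A cohort directory path or a `cohort` object.
#' @return `TRUE` if valid, `FALSE` otherwise (invisibly).
#' @export
validate_cohort <- function(x) {
  problems <- character()
  note <- function(level, msg) {
    problems <<- c(problems, msg)
    message(level, " ", msg)
  }
  co <- tryCatch({
    if (is.character(x)) read_cohort(x) else x
  }, error = function(e) {
    note("ERROR", conditionMessage(e))
    NULL
  })
  if (!is.null(co)) {
    message("INFO cohort: ", length(co$ethograms), " animal(s)")
    if (length(co$ethograms)) {
      nf <- vapply(co$ethograms, n_frames, 0L)
      if (length(unique(nf)) > 1)
        note("WARN", paste("unequal frame counts across animals:",
                           paste(range(nf), collapse = "-")))
    }
    dur <- if (length(co$ethograms))
      n_frames(co$ethograms[[1]]) / cohort_fps(co) else 0
    for (nm in names(co$stimuli$channels)) {
      ch <- co$stimuli$channels[[nm]]
      if (nrow(ch) && any(ch$offset_s > dur))
        note("WARN", paste0("channel ", nm, " has pulses beyond record end"))
    }
  }
  invisible(length(problems) == 0 && !is.null(co))
}
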