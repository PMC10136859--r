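#' Screen geometry of the presentation display
#'
#' Physical description of the stimulus display and viewing distance, needed
#' to convert normalized gaze coordinates into degrees of visual angle.
#' Defaults describe a 24-inch 16:9 monitor (531.3 x 298.9 mm active area,
#' 1280 x 720 px) viewed from 80 cm, the setup assumed throughout the
#' package.
#'
#' @param width_mm,height_mm Physical size of the active display area (mm).
#' @param res_x,res_y Pixel resolution.
#' @param distance_mm Eye-to-screen distance (mm).
#' @return An object of class `screen_geometry`.
#' @export
#' @examples
#' geom <- screen_geometry()
#' geom$distance_mm
screen_geometry <- function(width_mm = 531.3, height_mm = 298.9,
                            res_x = 1280, res_y = 720, distance_mm = 800) {
  vals <- c(width_mm, height_mm, res_x, res_y, distance_mm)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all screen geometry parameters must be strictly positive")
  structure(list(width_mm = width_mm, height_mm = height_mm,
                 res_x = res_x, res_y = res_y, distance_mm = distance_mm),
            class = "screen_geometry")
}

#' Construct a raw eye-tracking recording
#'
#' Container for one participant x video sample stream: timestamps, gaze in
#' normalized screen coordinates (origin bottom-left, x rightward, y upward,
#' on-screen range \[0,1\]), pupil diameter in mm (NA while the pupil is not
#' detected), per-sample detection confidence in \[0,1\], and tracker-reported
#' blink intervals.
#'
#' @param participant_id,video_id Identifiers.
#' @param t Timestamps in seconds from recording start, nondecreasing.
#' @param gaze_x,gaze_y Normalized gaze coordinates.
#' @param pupil_mm Pupil diameter (mm); NA where undetected.
#' @param confidence Detection confidence in \[0,1\].
#' @param blinks Two-column matrix or data.frame of blink `(start_s, end_s)`
#'   intervals; may have zero rows.
#' @param fs_hz Nominal sampling rate (Hz).
#' @param aborted Logical; `TRUE` if the viewer stopped playback early.
#' @param clip_duration_s Stimulus duration in seconds.
#' @return An object of class `raw_recording`.
#' @export
raw_recording <- function(participant_id, video_id, t, gaze_x, gaze_y,
                          pupil_mm, confidence, blinks = NULL,
                          fs_hz = 240, aborted = FALSE,
                          clip_duration_s = NULL) {
  n <- length(t)
  if (n < 2) stop("empty recording: fewer than 2 samples")
  lens <- c(length(gaze_x), length(gaze_y), length(pupil_mm),
            length(confidence))
  if (any(lens != n))
    stop("t, gaze_x, gaze_y, pupil_mm and confidence must have equal length")
  if (any(diff(t) < 0)) stop("timestamps must be nondecreasing")
  if (!is.finite(fs_hz) || fs_hz <= 0) stop("fs_hz must be positive")
  blinks <- normalize_blink_intervals(blinks, t[1], t[n])
  if (is.null(clip_duration_s)) clip_duration_s <- t[n] - t[1]
  structure(list(participant_id = as.character(participant_id),
                 video_id = as.character(video_id),
                 fs_hz = fs_hz, t = as.numeric(t),
                 gaze_x = as.numeric(gaze_x), gaze_y = as.numeric(gaze_y),
                 pupil_mm = as.numeric(pupil_mm),
                 confidence = as.numeric(confidence),
                 blinks = blinks, aborted = isTRUE(aborted),
                 clip_duration_s = clip_duration_s),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf(
    "<raw_recording> participant %s, video %s: %d samples @ %g Hz, %.1f s, %d blink interval(s)%s\n",
    x$participant_id, x$video_id, length(x$t), x$fs_hz,
    x$t[length(x$t)] - x$t[1], nrow(x$blinks),
    if (x$aborted) " [aborted]" else ""))
  invisible(x)
}

# Merge overlapping/adjacent intervals, clip to [lo, hi], drop empty ones.
normalize_blink_intervals <- function(blinks, lo, hi) {
  if (is.null(blinks) || NROW(blinks) == 0)
    return(matrix(numeric(0), ncol = 2,
                  dimnames = list(NULL, c("start_s", "end_s"))))
  b <- as.matrix(as.data.frame(blinks)[, 1:2])
  storage.mode(b) <- "double"
  b[, 1] <- pmax(b[, 1], lo)
  b[, 2] <- pmin(b[, 2], hi)
  b <- b[b[, 2] > b[, 1], , drop = FALSE]
  if (nrow(b) > 1) {
    b <- b[order(b[, 1]), , drop = FALSE]
    out <- b[1, , drop = FALSE]
    for (i in 2:nrow(b)) {
      if (b[i, 1] <= out[nrow(out), 2]) {
        out[nrow(out), 2] <- max(out[nrow(out), 2], b[i, 2])
      } else {
        out <- rbind(out, b[i, , drop = FALSE])
      }
    }
    b <- out
  }
  dimnames(b) <- list(NULL, c("start_s", "end_s"))
  b
}

.gaze_cols <- c("timestamp_s", "gaze_x_norm", "gaze_y_norm", "pupil_mm",
                "confidence")

#' Read a recording from its gaze and blink CSV files
#'
#' The gaze CSV must carry the header columns `timestamp_s, gaze_x_norm,
#' gaze_y_norm, pupil_mm, confidence` (any column order; extra columns are
#' ignored). The optional blink CSV carries `start_s, end_s`. Rows whose
#' timestamp or confidence cannot be parsed are dropped with a message;
#' unparseable gaze or pupil entries become NA.
#'
#' @param gaze_path Path to the gaze sample CSV.
#' @param blink_path Optional path to the blink interval CSV.
#' @param meta Optional list or one-row data.frame with `participant_id`,
#'   `video_id`, and optionally `emotion` and `duration_s` (a manifest row).
#' @param fs_hz Nominal sampling rate.
#' @param aborted Abort flag for the recording.
#' @return A [raw_recording()].
#' @export
read_recording <- function(gaze_path, blink_path = NULL, meta = NULL,
                           fs_hz = 240, aborted = FALSE) {
  d <- utils::read.csv(gaze_path, check.names = FALSE)
  missing_cols <- setdiff(.gaze_cols, names(d))
  if (length(missing_cols) > 0)
    stop("gaze file ", gaze_path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  d <- d[, .gaze_cols]
  for (cc in .gaze_cols) d[[cc]] <- suppressWarnings(as.numeric(d[[cc]]))
  keep <- is.finite(d$timestamp_s) & is.finite(d$confidence)
  if (any(!keep)) {
    message(sum(!keep), " unparseable row(s) dropped from ", gaze_path)
    d <- d[keep, ]
  }
  if (nrow(d) < 2)
    stop("empty recording: fewer than 2 valid samples in ", gaze_path)
  blinks <- NULL
  if (!is.null(blink_path)) {
    b <- utils::read.csv(blink_path, check.names = FALSE)
    if (!all(c("start_s", "end_s") %in% names(b)))
      stop("blink file ", blink_path, " must have columns start_s, end_s")
    blinks <- b[, c("start_s", "end_s")]
  }
  meta <- as.list(meta)
  raw_recording(
    participant_id = meta$participant_id %||% "unknown",
    video_id = meta$video_id %||% basename(gaze_path),
    t = d$timestamp_s, gaze_x = d$gaze_x_norm, gaze_y = d$gaze_y_norm,
    pupil_mm = d$pupil_mm, confidence = d$confidence, blinks = blinks,
    fs_hz = fs_hz, aborted = aborted,
    clip_duration_s = meta$duration_s %||% NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a recording to gaze and blink CSV files
#'
#' Inverse of [read_recording()]: numeric content survives a write/read
#' round trip at full double precision.
#'
#' @param rec A [raw_recording()].
#' @param gaze_path,blink_path Output paths (blink file optional).
#' @return `rec`, invisibly.
#' @export
write_recording <- function(rec, gaze_path, blink_path = NULL) {
  stopifnot(inherits(rec, "raw_recording"))
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))
  lines <- c(paste(.gaze_cols, collapse = ","),
             paste(fmt(rec$t), fmt(rec$gaze_x), fmt(rec$gaze_y),
                   fmt(rec$pupil_mm), fmt(rec$confidence), sep = ","))
  writeLines(lines, gaze_path)
  if (!is.null(blink_path)) {
    bl <- c("start_s,end_s",
            if (nrow(rec$blinks) > 0)
              paste(fmt(rec$blinks[, 1]), fmt(rec$blinks[, 2]), sep = ","))
    writeLines(bl, blink_path)
  }
  invisible(rec)
}

#' Read a session manifest
#'
#' @param path CSV with columns `participant_id, video_id, emotion,
#'   duration_s`; `(participant_id, video_id)` pairs must be unique and
#'   emotions drawn from anger, disgust, sadness, tenderness, neutral.
#' @return A data.frame.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, check.names = FALSE,
                       colClasses = c(participant_id = "character",
                                      video_id = "character"))
  req <- c("participant_id", "video_id", "emotion", "duration_s")
  if (!all(req %in% names(m)))
    stop("manifest must have columns ", paste(req, collapse = ", "))
  validate_manifest(m[, req])
}

validate_manifest <- function(m) {
  if (anyDuplicated(m[, c("participant_id", "video_id")]))
    stop("(participant_id, video_id) pairs must be unique in the manifest")
  bad <- setdiff(unique(m$emotion), .emotions)
  if (length(bad) > 0)
    stop("unknown emotion label(s) in manifest: ", paste(bad, collapse = ", "))
  m
}

.emotions <- c("anger", "disgust", "sadness", "tenderness", "neutral")

#' Recording validity filter
#'
#' Screens a recording against the exclusion rules applied before feature
#' extraction: a recording is excluded when the eyes were closed for more
#' than 10% of the clip duration, when gaze was off screen (the
#' mind-wandering proxy) for more than 20% of it, or when playback was
#' aborted. Boundary values exactly at 10%/20% are kept (the rules are
#' strict inequalities). Eyes-closed time is the union of tracker blink
#' intervals and contiguous low-confidence runs, clipped to the clip
#' window; the off-screen fraction counts samples outside the unit square
#' that do not fall inside eyes-closed time.
#'
#' @param rec A [raw_recording()].
#' @param closure_max Maximum tolerated eyes-closed fraction (default 0.10).
#' @param offscreen_max Maximum tolerated off-screen fraction (default 0.20).
#' @param confidence_threshold Confidence below which the pupil is
#'   considered undetected (eyes closed).
#' @return A list of class `validity_report` with `eyes_closed_fraction`,
#'   `offscreen_fraction`, `aborted`, `verdict` (`"kept"`/`"excluded"`) and
#'   `reasons`.
#' @export
validity_filter <- function(rec, closure_max = 0.10, offscreen_max = 0.20,
                            confidence_threshold = 0.5) {
  stopifnot(inherits(rec, "raw_recording"))
  if (!is.finite(rec$clip_duration_s) || rec$clip_duration_s <= 0)
    stop("clip_duration_s must be positive")
  closed_iv <- closure_intervals(rec, confidence_threshold)
  t0 <- rec$t[1]
  closed_time <- if (nrow(closed_iv) > 0) {
    s <- pmax(closed_iv[, 1], t0)
    e <- pmin(closed_iv[, 2], t0 + rec$clip_duration_s)
    sum(pmax(e - s, 0))
  } else 0
  eyes_closed_fraction <- min(closed_time / rec$clip_duration_s, 1)

  in_closed <- in_intervals(rec$t, closed_iv)
  off <- !in_closed &
    (!is.finite(rec$gaze_x) | !is.finite(rec$gaze_y) |
       rec$gaze_x < 0 | rec$gaze_x > 1 | rec$gaze_y < 0 | rec$gaze_y > 1)
  offscreen_fraction <- mean(off)

  reasons <- character(0)
  if (eyes_closed_fraction > closure_max)
    reasons <- c(reasons, sprintf("eye-closure > %.0f%%", 100 * closure_max))
  if (offscreen_fraction > offscreen_max)
    reasons <- c(reasons, sprintf("off-screen > %.0f%%", 100 * offscreen_max))
  if (rec$aborted) reasons <- c(reasons, "playback aborted")
  structure(list(participant_id = rec$participant_id,
                 video_id = rec$video_id,
                 eyes_closed_fraction = eyes_closed_fraction,
                 offscreen_fraction = offscreen_fraction,
                 aborted = rec$aborted,
                 verdict = if (length(reasons)) "excluded" else "kept",
                 reasons = reasons),
            class = "validity_report")
}

#' @export
print.validity_report <- function(x, ...) {
  cat(sprintf("<validity_report> %s/%s: %s (closed %.1f%%, off-screen %.1f%%)%s\n",
              x$participant_id, x$video_id, x$verdict,
              100 * x$eyes_closed_fraction, 100 * x$offscreen_fraction,
              if (length(x$reasons))
                paste0("\n  reasons: ", paste(x$reasons, collapse = "; "))
              else ""))
  invisible(x)
}

# Union of tracker blink intervals and contiguous low-confidence runs.
closure_intervals <- function(rec, confidence_threshold) {
  low <- rec$confidence < confidence_threshold
  iv <- runs_to_intervals(low, rec$t)
  normalize_blink_intervals(rbind(rec$blinks, iv),
                            rec$t[1], rec$t[length(rec$t)])
}

# TRUE-runs of a logical vector as (start, end) time intervals. A run of k
# flagged samples spans k sample periods: the interval extends to the next
# unflagged sample (capped at the series end).
runs_to_intervals <- function(flag, t) {
  flag[is.na(flag)] <- FALSE
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  cbind(start_s = t[starts[keep]],
        end_s = t[pmin(ends[keep] + 1, length(t))])
}

# Which elements of x fall inside any [start, end] interval
# (open intervals when strict).
in_intervals <- function(x, iv, strict = FALSE) {
  if (NROW(iv) == 0) return(rep(FALSE, length(x)))
  out <- rep(FALSE, length(x))
  for (i in seq_len(nrow(iv)))
    out <- out | if (strict) (x > iv[i, 1] & x < iv[i, 2])
                 else (x >= iv[i, 1] & x <= iv[i, 2])
  out
}

#' Apply the validity filter to a whole session
#'
#' @param recordings List of [raw_recording()] objects.
#' @param ... Passed to [validity_filter()].
#' @return A data.frame with one row per recording (verdict, fractions,
#'   reasons). Kept plus excluded rows always partition the input.
#' @export
filter_session <- function(recordings, ...) {
  reps <- lapply(recordings, validity_filter, ...)
  data.frame(
    participant_id = vapply(reps, `[[`, "", "participant_id"),
    video_id = vapply(reps, `[[`, "", "video_id"),
    eyes_closed_fraction = vapply(reps, `[[`, 0, "eyes_closed_fraction"),
    offscreen_fraction = vapply(reps, `[[`, 0, "offscreen_fraction"),
    aborted = vapply(reps, `[[`, FALSE, "aborted"),
    verdict = vapply(reps, `[[`, "", "verdict"),
    reasons = vapply(reps, function(r) paste(r$reasons, collapse = "; "), ""),
    stringsAsFactors = FALSE)
}

#' Load a local copy of the eSEE-d archive
#'
#' Maps a locally downloaded copy of the deposited eSEE-d dataset
#' (Zenodo accession 10.5281/zenodo.5775674) into the package's recording
#' model. The archive must first be unpacked and exported to the package's
#' CSV schemas (one gaze and one blink CSV per recording plus `manifest.csv`
#' and `ratings.csv` at the root); the raw Pupil Capture exports carry the
#' same information under different column names and are straightforward to
#' rename. The test suite never calls this function.
#'
#' @param root Directory holding `manifest.csv`, `ratings.csv` and
#'   `<participant>_<video>_gaze.csv` / `_blinks.csv` files.
#' @return A list with `recordings` (list of [raw_recording()]), `manifest`
#'   and `ratings` data.frames.
#' @export
load_esee_d <- function(root) {
  if (!dir.exists(root))
    stop("dataset not present at '", root, "'. Download the eSEE-d archive ",
         "(DOI: 10.5281/zenodo.5775674), unpack it, and export it to the ",
         "documented CSV layout.")
  manifest <- read_manifest(file.path(root, "manifest.csv"))
  ratings <- utils::read.csv(file.path(root, "ratings.csv"),
                             check.names = FALSE)
  recs <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    stem <- file.path(root, paste0(manifest$participant_id[i], "_",
                                   manifest$video_id[i]))
    bp <- paste0(stem, "_blinks.csv")
    recs[[i]] <- read_recording(paste0(stem, "_gaze.csv"),
                                if (file.exists(bp)) bp else NULL,
                                meta = manifest[i, ])
  }
  list(recordings = recs, manifest = manifest, ratings = ratings)
}
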