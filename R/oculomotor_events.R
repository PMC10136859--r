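#' Event detector configuration
#'
#' Thresholds for the velocity-threshold (I-VT) fixation/saccade detector
#' and the confidence-based blink detector. Defaults: 45 deg/s saccade
#' velocity cut, 55 ms minimum fixation duration, 0.5 confidence cut for
#' pupil-loss blink detection.
#'
#' @param velocity_threshold_deg_s Speed at or above which a sample pair is
#'   a saccade point (fixation requires speed strictly below).
#' @param min_fixation_ms Fixation groups shorter than this are discarded
#'   as unclassified gaps.
#' @param blink_confidence_threshold Confidence below which the pupil is
#'   considered lost.
#' @return An `event_detector_config` list.
#' @export
event_detector_config <- function(velocity_threshold_deg_s = 45,
                                  min_fixation_ms = 55,
                                  blink_confidence_threshold = 0.5) {
  vals <- c(velocity_threshold_deg_s, min_fixation_ms,
            blink_confidence_threshold)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all detector thresholds must be positive")
  structure(list(velocity_threshold_deg_s = velocity_threshold_deg_s,
                 min_fixation_ms = min_fixation_ms,
                 blink_confidence_threshold = blink_confidence_threshold),
            class = "event_detector_config")
}

#' Per-interval I-VT labels
#'
#' Classifies every sample-to-sample speed interval: `"saccade"` when the
#' speed is at or above the velocity threshold, `"fixation"` when strictly
#' below, `"invalid"` when the interval touches a masked sample.
#'
#' @param series An `angular_gaze` series with `speed` computed.
#' @param cfg An [event_detector_config()].
#' @return Character vector of length `n - 1`.
#' @export
ivt_labels <- function(series, cfg = event_detector_config()) {
  sp <- series$speed
  lab <- rep("invalid", length(sp))
  ok <- series$speed_valid & !is.na(sp)
  lab[ok & sp >= cfg$velocity_threshold_deg_s] <- "saccade"
  lab[ok & sp < cfg$velocity_threshold_deg_s] <- "fixation"
  lab
}

#' Segment an angular gaze series into fixations and saccades (I-VT)
#'
#' Implements velocity-threshold identification with a minimum fixation
#' duration: every speed interval is labeled fixation (below threshold) or
#' saccade (at/above threshold); maximal runs of fixation intervals are
#' collapsed into fixation groups; groups shorter than the minimum duration
#' are discarded as unclassified gaps (not merged into saccades); each
#' surviving group becomes a fixation at the centroid (arithmetic mean) of
#' its angular positions. Maximal runs of saccade intervals become saccades
#' whose amplitude is the great-circle angle between the run's two boundary
#' samples and whose mean/peak velocity summarize the run's speeds. A run
#' of `k` intervals spans `k + 1` samples, so consecutive events share
#' boundary samples and durations are `k / fs`.
#'
#' @param series An `angular_gaze` series with `speed` computed (filtered
#'   or raw).
#' @param cfg An [event_detector_config()].
#' @return An `oculomotor_events` object with data.frames `fixations`
#'   (`start_s, end_s, duration_ms, centroid_x_deg, centroid_y_deg`),
#'   `saccades` (`start_s, end_s, duration_ms, amplitude_deg,
#'   mean_velocity_deg_s, peak_velocity_deg_s`), an empty `blinks` slot and
#'   `recording_duration_s`.
#' @export
ivt_segment <- function(series, cfg = event_detector_config()) {
  stopifnot(inherits(series, "angular_gaze"))
  n <- length(series$t)
  empty <- oculomotor_events(
    fixations = NULL, saccades = NULL, blinks = NULL,
    recording_duration_s = if (n >= 2) series$t[n] - series$t[1] else 0)
  if (n < 2 || is.null(series$speed)) return(empty)

  lab <- ivt_labels(series, cfg)
  r <- rle(lab)
  ends <- cumsum(r$lengths)        # interval indices
  starts <- ends - r$lengths + 1
  t <- series$t

  fx <- which(r$values == "fixation")
  fixations <- NULL
  if (length(fx) > 0) {
    s_smp <- starts[fx]            # run of intervals i..j spans samples i..j+1
    e_smp <- ends[fx] + 1
    dur_ms <- (t[e_smp] - t[s_smp]) * 1000
    keep <- dur_ms >= cfg$min_fixation_ms
    if (any(keep)) {
      s_smp <- s_smp[keep]; e_smp <- e_smp[keep]
      fixations <- data.frame(
        start_s = t[s_smp], end_s = t[e_smp], duration_ms = dur_ms[keep],
        centroid_x_deg = mapply(function(a, b) mean(series$theta_x[a:b]),
                                s_smp, e_smp),
        centroid_y_deg = mapply(function(a, b) mean(series$theta_y[a:b]),
                                s_smp, e_smp))
    }
  }

  sc <- which(r$values == "saccade")
  saccades <- NULL
  if (length(sc) > 0) {
    s_smp <- starts[sc]
    e_smp <- ends[sc] + 1
    u <- gaze_direction_vectors(series$theta_x[s_smp], series$theta_y[s_smp])
    v <- gaze_direction_vectors(series$theta_x[e_smp], series$theta_y[e_smp])
    saccades <- data.frame(
      start_s = t[s_smp], end_s = t[e_smp],
      duration_ms = (t[e_smp] - t[s_smp]) * 1000,
      amplitude_deg = great_angle_deg(u, v),
      mean_velocity_deg_s = mapply(
        function(a, b) mean(series$speed[a:b]), starts[sc], ends[sc]),
      peak_velocity_deg_s = mapply(
        function(a, b) max(series$speed[a:b]), starts[sc], ends[sc]))
  }

  oculomotor_events(fixations, saccades, NULL,
                    recording_duration_s = t[n] - t[1])
}

#' Assemble blink events for a recording
#'
#' Uses the tracker-provided blink intervals when present; otherwise
#' derives blinks as maximal runs of samples whose confidence falls below
#' the blink confidence threshold. Overlapping or adjacent intervals are
#' merged.
#'
#' @param rec A [raw_recording()].
#' @param cfg An [event_detector_config()].
#' @return A data.frame `start_s, end_s, duration_ms` (possibly 0 rows).
#' @export
assemble_blinks <- function(rec, cfg = event_detector_config()) {
  stopifnot(inherits(rec, "raw_recording"))
  iv <- if (nrow(rec$blinks) > 0) {
    rec$blinks
  } else {
    normalize_blink_intervals(
      runs_to_intervals(rec$confidence < cfg$blink_confidence_threshold,
                        rec$t),
      rec$t[1], rec$t[length(rec$t)])
  }
  data.frame(start_s = iv[, 1], end_s = iv[, 2],
             duration_ms = (iv[, 2] - iv[, 1]) * 1000)
}

#' Oculomotor event container
#'
#' @param fixations,saccades,blinks Event data.frames (or NULL for none).
#' @param recording_duration_s Length of the underlying recording (s).
#' @return An `oculomotor_events` object.
#' @export
oculomotor_events <- function(fixations, saccades, blinks,
                              recording_duration_s) {
  empty_fix <- data.frame(start_s = numeric(0), end_s = numeric(0),
                          duration_ms = numeric(0),
                          centroid_x_deg = numeric(0),
                          centroid_y_deg = numeric(0))
  empty_sac <- data.frame(start_s = numeric(0), end_s = numeric(0),
                          duration_ms = numeric(0),
                          amplitude_deg = numeric(0),
                          mean_velocity_deg_s = numeric(0),
                          peak_velocity_deg_s = numeric(0))
  empty_blk <- data.frame(start_s = numeric(0), end_s = numeric(0),
                          duration_ms = numeric(0))
  structure(list(fixations = fixations %||% empty_fix,
                 saccades = saccades %||% empty_sac,
                 blinks = blinks %||% empty_blk,
                 recording_duration_s = recording_duration_s),
            class = "oculomotor_events")
}

#' @export
print.oculomotor_events <- function(x, ...) {
  cat(sprintf(
    "<oculomotor_events> %.1f s: %d fixation(s), %d saccade(s), %d blink(s)\n",
    x$recording_duration_s, nrow(x$fixations), nrow(x$saccades),
    nrow(x$blinks)))
  invisible(x)
}

#' Detect all oculomotor events in a recording
#'
#' Full event-detection chain: gaze preprocessing ([preprocess_gaze()]),
#' I-VT fixation/saccade segmentation ([ivt_segment()]) and blink assembly
#' ([assemble_blinks()]). Samples inside blinks are masked before
#' segmentation so blink artifacts do not register as saccades.
#'
#' @param rec A [raw_recording()].
#' @param geom A [screen_geometry()].
#' @param cfg An [event_detector_config()].
#' @param filter_method Velocity filter method (see
#'   [five_tap_velocity_filter()]); `"none"` disables filtering.
#' @return An `oculomotor_events` object.
#' @export
detect_events <- function(rec, geom = screen_geometry(),
                          cfg = event_detector_config(),
                          filter_method = c("median", "mean", "none")) {
  series <- preprocess_gaze(rec, geom, cfg$blink_confidence_threshold,
                            match.arg(filter_method))
  ev <- ivt_segment(series, cfg)
  ev$blinks <- assemble_blinks(rec, cfg)
  ev
}

#' Serialize oculomotor events to JSON
#'
#' @param events An `oculomotor_events` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events_json <- function(events, path) {
  jsonlite::write_json(
    list(recording_duration_s = events$recording_duration_s,
         fixations = events$fixations, saccades = events$saccades,
         blinks = events$blinks),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
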