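#' The 28-feature schema
#'
#' Stable names of the 28 eye and gaze features extracted per recording:
#' fixation frequency and fixation-duration median/CV/skewness/kurtosis;
#' saccade frequency and saccade duration, amplitude, mean velocity and
#' peak velocity summaries; blink frequency and mean blink duration; and
#' pupil-diameter mean/CV/skewness/kurtosis. Duration-like central values
#' are medians for fixation duration, saccade duration and saccade
#' amplitude, and means for saccade velocity, peak velocity, blink duration
#' and pupil diameter.
#'
#' @return Character vector of 28 feature names.
#' @export
feature_schema <- function() {
  c("fix_freq", "fix_dur_median", "fix_dur_cv", "fix_dur_skew",
    "fix_dur_kurt",
    "sac_freq", "sac_dur_median", "sac_dur_cv", "sac_dur_skew",
    "sac_dur_kurt",
    "sac_amp_median", "sac_amp_cv", "sac_amp_skew", "sac_amp_kurt",
    "sac_vel_mean", "sac_vel_cv", "sac_vel_skew", "sac_vel_kurt",
    "sac_pvel_mean", "sac_pvel_cv", "sac_pvel_skew", "sac_pvel_kurt",
    "blink_freq", "blink_dur_mean",
    "pupil_mean", "pupil_cv", "pupil_skew", "pupil_kurt")
}

#' Distributional summary of a sample
#'
#' Central value, coefficient of variation, skewness and kurtosis of a
#' numeric sample, the summary applied to every event-metric family.
#' CV is the sample standard deviation (n-1 denominator) over the mean;
#' skewness is the Fisher-Pearson sample skewness `m3 / m2^1.5`; kurtosis
#' defaults to excess kurtosis `m4 / m2^2 - 3` (set `excess_kurtosis =
#' FALSE` for the raw fourth standardized moment). Zero-variance samples
#' get skewness 0 and kurtosis NA with a warning; samples of size < 2 get
#' NA dispersion/shape statistics; a zero mean gives NA CV.
#'
#' @param x Numeric sample (NAs dropped).
#' @param central `"median"` or `"mean"`.
#' @param excess_kurtosis Report excess (default) or raw kurtosis.
#' @return Named numeric vector `(central, cv, skewness, kurtosis)`.
#' @export
summary_stats <- function(x, central = c("median", "mean"),
                          excess_kurtosis = TRUE) {
  central <- match.arg(central)
  x <- x[is.finite(x)]
  n <- length(x)
  if (n == 0)
    return(c(central = NA_real_, cv = NA_real_, skewness = NA_real_,
             kurtosis = NA_real_))
  ctr <- if (central == "median") stats::median(x) else mean(x)
  if (n < 2)
    return(c(central = ctr, cv = NA_real_, skewness = NA_real_,
             kurtosis = NA_real_))
  mu <- mean(x)
  s <- stats::sd(x)
  cv <- if (mu == 0) NA_real_ else s / mu
  m2 <- mean((x - mu)^2)
  if (m2 == 0) {
    warning("zero-variance sample: skewness reported as 0")
    skew <- 0
    kurt <- NA_real_
  } else {
    skew <- mean((x - mu)^3) / m2^1.5
    kurt <- mean((x - mu)^4) / m2^2 - if (excess_kurtosis) 3 else 0
  }
  c(central = ctr, cv = cv, skewness = skew, kurtosis = kurt)
}

#' Extract the 28 eye and gaze features of one recording
#'
#' Event frequencies are event counts divided by the full recording
#' duration; duration/amplitude/velocity summaries come from
#' [summary_stats()] with the family's central statistic; pupil statistics
#' are computed over samples outside blink intervals whose confidence is at
#' or above the blink threshold. Feature families whose events are absent
#' are NA (never silently zero).
#'
#' @param events An `oculomotor_events` object for the recording.
#' @param rec The [raw_recording()] the events came from (pupil series).
#' @param cfg The [event_detector_config()] used (confidence threshold for
#'   pupil masking).
#' @param excess_kurtosis Kurtosis convention, see [summary_stats()].
#' @return A named numeric vector of class `feature_vector` with exactly
#'   the 28 entries of [feature_schema()].
#' @export
extract_features <- function(events, rec, cfg = event_detector_config(),
                             excess_kurtosis = TRUE) {
  stopifnot(inherits(events, "oculomotor_events"),
            inherits(rec, "raw_recording"))
  dur <- events$recording_duration_s
  if (!is.finite(dur) || dur <= 0) stop("recording duration must be positive")

  ss <- function(x, central) {
    suppressWarnings(summary_stats(x, central, excess_kurtosis))
  }
  fix <- ss(events$fixations$duration_ms, "median")
  sdur <- ss(events$saccades$duration_ms, "median")
  samp <- ss(events$saccades$amplitude_deg, "median")
  svel <- ss(events$saccades$mean_velocity_deg_s, "mean")
  spvel <- ss(events$saccades$peak_velocity_deg_s, "mean")

  in_blink <- in_intervals(rec$t, as.matrix(events$blinks[, 1:2, drop = FALSE]))
  pup <- rec$pupil_mm[!in_blink &
                        rec$confidence >= cfg$blink_confidence_threshold]
  pstat <- ss(pup, "mean")

  nfix <- nrow(events$fixations)
  nsac <- nrow(events$saccades)
  nblk <- nrow(events$blinks)
  if (nfix == 0) message("recording has no fixations; features set to NA")
  if (nsac == 0) message("recording has no saccades; features set to NA")
  if (nblk == 0) message("recording has no blinks; features set to NA")

  v <- c(
    fix_freq = if (nfix > 0) nfix / dur else NA_real_,
    fix_dur_median = fix[["central"]], fix_dur_cv = fix[["cv"]],
    fix_dur_skew = fix[["skewness"]], fix_dur_kurt = fix[["kurtosis"]],
    sac_freq = if (nsac > 0) nsac / dur else NA_real_,
    sac_dur_median = sdur[["central"]], sac_dur_cv = sdur[["cv"]],
    sac_dur_skew = sdur[["skewness"]], sac_dur_kurt = sdur[["kurtosis"]],
    sac_amp_median = samp[["central"]], sac_amp_cv = samp[["cv"]],
    sac_amp_skew = samp[["skewness"]], sac_amp_kurt = samp[["kurtosis"]],
    sac_vel_mean = svel[["central"]], sac_vel_cv = svel[["cv"]],
    sac_vel_skew = svel[["skewness"]], sac_vel_kurt = svel[["kurtosis"]],
    sac_pvel_mean = spvel[["central"]], sac_pvel_cv = spvel[["cv"]],
    sac_pvel_skew = spvel[["skewness"]], sac_pvel_kurt = spvel[["kurtosis"]],
    blink_freq = if (nblk > 0) nblk / dur else NA_real_,
    blink_dur_mean = if (nblk > 0) mean(events$blinks$duration_ms)
                     else NA_real_,
    pupil_mean = pstat[["central"]], pupil_cv = pstat[["cv"]],
    pupil_skew = pstat[["skewness"]], pupil_kurt = pstat[["kurtosis"]])
  stopifnot(identical(names(v), feature_schema()))
  class(v) <- c("feature_vector", "numeric")
  v
}

#' @export
print.feature_vector <- function(x, ...) {
  cat("<feature_vector> 28 eye/gaze features\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Extract features for a batch of recordings
#'
#' Runs [detect_events()] and [extract_features()] over a list of
#' recordings and assembles a feature table.
#'
#' @param recordings List of [raw_recording()] objects.
#' @param geom,cfg,filter_method Passed to [detect_events()].
#' @return A data.frame: `participant_id`, `video_id`, then the 28 feature
#'   columns.
#' @export
extract_features_batch <- function(recordings, geom = screen_geometry(),
                                   cfg = event_detector_config(),
                                   filter_method = "median") {
  rows <- lapply(recordings, function(rec) {
    ev <- detect_events(rec, geom, cfg, filter_method)
    fv <- suppressMessages(extract_features(ev, rec, cfg))
    cbind(data.frame(participant_id = rec$participant_id,
                     video_id = rec$video_id, stringsAsFactors = FALSE),
          as.data.frame(t(unclass(fv))))
  })
  do.call(rbind, rows)
}
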