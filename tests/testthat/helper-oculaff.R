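# Shared fixture builders (everything is generated in code at test time).

# Minimal constant-gaze recording: n samples at fs Hz, gaze at screen
# center, full confidence, pupil 4 mm.
make_toy_recording <- function(n = 240, fs = 240, gaze_x = 0.5,
                               gaze_y = 0.5, confidence = 1, pupil = 4,
                               blinks = NULL, clip_duration_s = NULL,
                               aborted = FALSE) {
  t <- (seq_len(n) - 1) / fs
  raw_recording("P01", "v01", t = t,
                gaze_x = rep_len(gaze_x, n), gaze_y = rep_len(gaze_y, n),
                pupil_mm = rep_len(pupil, n),
                confidence = rep_len(confidence, n), blinks = blinks,
                fs_hz = fs, aborted = aborted,
                clip_duration_s = clip_duration_s)
}

# Fabricated angular series with injected speeds (for label-rule tests).
make_speed_series <- function(speed, fs = 240) {
  n <- length(speed) + 1
  structure(list(t = (seq_len(n) - 1) / fs, theta_x = rep(0, n),
                 theta_y = rep(0, n), valid = rep(TRUE, n),
                 on_screen = rep(TRUE, n), fs_hz = fs,
                 speed = speed, speed_valid = rep(TRUE, length(speed))),
            class = "angular_gaze")
}

# Memoised Monte-Carlo class batches used by the recovery and classifier
# acceptance checks: 28-column feature tables from freshly generated
# recordings (recordings are discarded to keep memory flat).
.batch_cache <- new.env(parent = emptyenv())

class_feature_batch <- function(label, n = 200, duration_s = 60,
                                seed_base = 589) {
  key <- paste(label, n, duration_s, sep = "_")
  if (!is.null(.batch_cache[[key]])) return(.batch_cache[[key]])
  set.seed(seed_base + match(label, c("LA", "MA", "HA", "NV", "MV", "PV",
                                      "HANV", "LANV", "LAPV", "MAMV")))
  prof <- packaged_profile(label)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    g <- generate_recording(prof, duration_s = duration_s)
    ev <- detect_events(g$recording)
    rows[[i]] <- as.data.frame(t(unclass(
      suppressMessages(extract_features(ev, g$recording)))))
  }
  out <- do.call(rbind, rows)
  .batch_cache[[key]] <- out
  out
}
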