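test_that("a steady gaze yields one long fixation and no saccade", {
  rec <- make_toy_recording(n = 240, fs = 240)
  ev <- detect_events(rec)
  expect_equal(nrow(ev$fixations), 1)
  expect_equal(nrow(ev$saccades), 0)
  # 240 samples span 239 sample periods ~ 996 ms
  expect_equal(ev$fixations$duration_ms, 239 / 240 * 1000)
  expect_equal(ev$fixations$centroid_x_deg, 0)
})

test_that("fixation requires speed strictly below the threshold", {
  lab <- ivt_labels(make_speed_series(c(44.999, 45, 45.001)))
  expect_equal(lab, c("fixation", "saccade", "saccade"))
})

test_that("sub-minimum fixation groups are discarded, not reassigned", {
  # 10 below-threshold intervals at 240 Hz (41.7 ms < 55 ms) flanked by
  # saccade points
  sp <- c(rep(300, 6), rep(5, 10), rep(300, 6))
  ev <- ivt_segment(make_speed_series(sp))
  expect_equal(nrow(ev$fixations), 0)
  expect_equal(nrow(ev$saccades), 2)   # the gap does not merge the runs

  # 14 intervals (58.3 ms) survive
  sp2 <- c(rep(300, 6), rep(5, 14), rep(300, 6))
  ev2 <- ivt_segment(make_speed_series(sp2))
  expect_equal(nrow(ev2$fixations), 1)
  expect_equal(ev2$fixations$duration_ms, 14 / 240 * 1000)
})

test_that("I-VT labels equal a brute-force threshold comparison", {
  set.seed(21)
  for (i in 1:25) {
    sp <- rexp(200, 1 / 60)
    cfg <- event_detector_config(velocity_threshold_deg_s = runif(1, 20, 90))
    lab <- ivt_labels(make_speed_series(sp), cfg)
    # independent oracle: per-sample comparison
    oracle <- ifelse(sp >= cfg$velocity_threshold_deg_s, "saccade",
                     "fixation")
    expect_identical(lab, oracle)
  }
})

test_that("raising the velocity threshold never loses fixation points", {
  set.seed(8)
  sp <- make_speed_series(rexp(500, 1 / 50))
  counts <- vapply(c(20, 45, 70, 120), function(vt)
    sum(ivt_labels(sp, event_detector_config(vt)) == "fixation"),
    numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("blink assembly uses provided intervals, merges, and falls back
           to confidence runs", {
  rec <- make_toy_recording(n = 960, blinks = cbind(1.0, 1.2))
  b <- assemble_blinks(rec)
  expect_equal(nrow(b), 1)
  expect_equal(b$duration_ms, 200)

  # overlapping inputs merge to their union
  rec2 <- make_toy_recording(n = 960, blinks = cbind(c(1.0, 1.1),
                                                     c(1.2, 1.3)))
  b2 <- assemble_blinks(rec2)
  expect_equal(nrow(b2), 1)
  expect_equal(c(b2$start_s, b2$end_s), c(1.0, 1.3))

  # no provided intervals: 30 low-confidence samples at 240 Hz -> 125 ms
  conf <- rep(1, 960); conf[101:130] <- 0.2
  rec3 <- make_toy_recording(n = 960, confidence = conf)
  b3 <- assemble_blinks(rec3)
  expect_equal(nrow(b3), 1)
  expect_equal(b3$duration_ms, 30 / 240 * 1000)
})

test_that("event durations tile a synthetic recording exactly", {
  g <- generate_recording(packaged_profile("MAMV"), duration_s = 15,
                          seed = 33)
  ev <- detect_events(g$recording)
  total <- (sum(ev$fixations$duration_ms) + sum(ev$saccades$duration_ms) +
              sum(ev$blinks$duration_ms)) / 1000
  expect_equal(total, ev$recording_duration_s, tolerance = 1e-9)
})

test_that("detection recovers ground truth on noiseless traces", {
  for (s in 1:3) {
    g <- generate_recording(packaged_profile("HANV"), duration_s = 12,
                            seed = 100 + s, motion_noise = FALSE)
    ev <- detect_events(g$recording)
    gt <- g$ground_truth
    expect_equal(nrow(ev$fixations), gt$n_fix)
    expect_equal(nrow(ev$saccades), gt$n_sac)
    expect_equal(nrow(ev$blinks), gt$n_blink)
    fx <- gt$events[gt$events$type == "fixation", ]
    one <- 1 / g$recording$fs_hz
    expect_true(all(abs(fx$start_s - ev$fixations$start_s) <= one))
    expect_true(all(abs(fx$end_s - ev$fixations$end_s) <= one))
  }
})

test_that("empty series yield empty event lists", {
  s <- make_speed_series(numeric(0))
  s$t <- 0; s$theta_x <- 0; s$theta_y <- 0   # single-sample series
  ev <- ivt_segment(s)
  expect_equal(nrow(ev$fixations), 0)
  expect_equal(nrow(ev$saccades), 0)
})
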