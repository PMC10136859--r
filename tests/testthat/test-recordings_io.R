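test_that("recordings survive a write/read round trip at full precision", {
  set.seed(42)
  n <- 50
  rec <- raw_recording("P07", "v03", t = (0:(n - 1)) / 240,
                       gaze_x = runif(n), gaze_y = runif(n),
                       pupil_mm = replace(rnorm(n, 4, 0.3), c(5, 9), NA),
                       confidence = runif(n, 0.4, 1),
                       blinks = cbind(c(0.02, 0.10), c(0.05, 0.13)),
                       clip_duration_s = 0.2)
  gp <- withr::local_tempfile(fileext = ".csv")
  bp <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, gp, bp)
  back <- read_recording(gp, bp, meta = list(participant_id = "P07",
                                             video_id = "v03",
                                             duration_s = 0.2))
  for (f in c("t", "gaze_x", "gaze_y", "pupil_mm", "confidence"))
    expect_identical(back[[f]], rec[[f]])
  expect_identical(back$blinks, rec$blinks)
})

test_that("gaze parsing is header-driven, not order-driven", {
  gp1 <- withr::local_tempfile(fileext = ".csv")
  gp2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp_s,gaze_x_norm,gaze_y_norm,pupil_mm,confidence",
               "0,0.5,0.5,4,1", "0.004,0.6,0.4,4.1,0.9",
               "0.008,0.7,0.3,4.2,0.8"), gp1)
  writeLines(c("confidence,pupil_mm,gaze_y_norm,gaze_x_norm,timestamp_s",
               "1,4,0.5,0.5,0", "0.9,4.1,0.4,0.6,0.004",
               "0.8,4.2,0.3,0.7,0.008"), gp2)
  r1 <- read_recording(gp1)
  r2 <- read_recording(gp2)
  expect_equal(length(r1$t), 3)
  for (f in c("t", "gaze_x", "gaze_y", "pupil_mm", "confidence"))
    expect_identical(r1[[f]], r2[[f]])
})

test_that("malformed gaze files raise the documented errors", {
  gp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp_s,gaze_x_norm,gaze_y_norm,pupil_mm",
               "0,0.5,0.5,4"), gp)
  expect_error(read_recording(gp), "missing required column")
  writeLines(c("timestamp_s,gaze_x_norm,gaze_y_norm,pupil_mm,confidence",
               "0,0.5,0.5,4,1", "oops,0.6,0.4,4,1"), gp)
  expect_error(suppressMessages(read_recording(gp)), "fewer than 2 valid")
})

test_that("validity filter applies the 10%/20%/abort exclusion rules", {
  # 15% eye closure -> excluded for closure
  rec <- make_toy_recording(n = 2400, fs = 240, clip_duration_s = 10,
                            blinks = cbind(2, 3.5))
  rep1 <- validity_filter(rec)
  expect_equal(rep1$eyes_closed_fraction, 0.15)
  expect_equal(rep1$verdict, "excluded")
  expect_match(rep1$reasons, "eye-closure", all = FALSE)

  # clean recording -> kept
  rep2 <- validity_filter(make_toy_recording(n = 2400, clip_duration_s = 10))
  expect_equal(rep2$verdict, "kept")
  expect_length(rep2$reasons, 0)

  # 25% of samples off screen -> excluded for off-screen
  gx <- rep(0.5, 2400); gx[1:600] <- 1.4
  rec3 <- make_toy_recording(n = 2400, gaze_x = gx, clip_duration_s = 10)
  rep3 <- validity_filter(rec3)
  expect_equal(rep3$offscreen_fraction, 0.25)
  expect_equal(rep3$verdict, "excluded")
  expect_match(rep3$reasons, "off-screen", all = FALSE)

  # aborted playback -> excluded regardless of signal quality
  expect_equal(validity_filter(make_toy_recording(n = 480,
                                                  clip_duration_s = 2,
                                                  aborted = TRUE))$verdict,
               "excluded")

  # boundary values are kept: the rules are strict inequalities
  rec5 <- make_toy_recording(n = 2400, clip_duration_s = 10,
                             blinks = cbind(2, 3))
  expect_equal(validity_filter(rec5)$eyes_closed_fraction, 0.10)
  expect_equal(validity_filter(rec5)$verdict, "kept")
})

test_that("filtering conserves recordings and closure is monotone", {
  set.seed(7)
  recs <- lapply(1:12, function(i) {
    cl <- runif(1, 0, 2.5)
    make_toy_recording(n = 2400, clip_duration_s = 10,
                       blinks = if (cl > 0) cbind(1, 1 + cl) else NULL)
  })
  tab <- filter_session(recs)
  expect_equal(nrow(tab), 12)
  expect_true(all(tab$verdict %in% c("kept", "excluded")))
  expect_equal(sum(tab$verdict == "kept") + sum(tab$verdict == "excluded"),
               12)
  # growing the closure interval can only flip kept -> excluded
  for (cl in seq(0.5, 3, by = 0.5)) {
    v1 <- validity_filter(make_toy_recording(n = 2400, clip_duration_s = 10,
                                             blinks = cbind(1, 1 + cl)))
    v2 <- validity_filter(make_toy_recording(n = 2400, clip_duration_s = 10,
                                             blinks = cbind(1, 1.5 + cl)))
    expect_false(v1$verdict == "excluded" && v2$verdict == "kept")
  }
})

test_that("manifest validation enforces uniqueness and the emotion set", {
  m <- data.frame(participant_id = c("P01", "P01"),
                  video_id = c("v01", "v02"),
                  emotion = c("anger", "neutral"), duration_s = c(60, 40))
  expect_silent(validate_manifest(m))
  m2 <- m; m2$video_id <- c("v01", "v01")
  expect_error(validate_manifest(m2), "unique")
  m3 <- m; m3$emotion[1] <- "joy"
  expect_error(validate_manifest(m3), "unknown emotion")
})

test_that("the archive loader reports a missing dataset clearly", {
  expect_error(load_esee_d(file.path(tempdir(), "no-such-dir")),
               "10.5281/zenodo.5775674", fixed = TRUE)
})
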