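test_that("the DES annotation rule resolves ratings as specified", {
  # clear winner above 4 with a >= 1 point lead
  a <- subjective_annotation(c(anger = 7.7, disgust = 4.5, sadness = 5.7,
                               tenderness = 0.2))
  expect_equal(a$emotion, "anger")
  expect_equal(a$quadrant, "HANV")

  # all scores below 4 -> neutral
  n1 <- subjective_annotation(c(anger = 3, disgust = 3, sadness = 3,
                                tenderness = 3))
  expect_equal(n1$emotion, "neutral")
  expect_equal(n1$quadrant, "MAMV")

  # top score not a full point ahead -> neutral
  n2 <- subjective_annotation(c(anger = 5, disgust = 4.5, sadness = 0,
                                tenderness = 0))
  expect_equal(n2$emotion, "neutral")

  # exact tie at the top -> neutral
  n3 <- subjective_annotation(c(anger = 6, disgust = 6, sadness = 0,
                                tenderness = 0))
  expect_equal(n3$emotion, "neutral")

  # exactly 1 point ahead counts ("at least 1 point")
  a2 <- subjective_annotation(c(anger = 5, disgust = 4, sadness = 0,
                                tenderness = 0))
  expect_equal(a2$emotion, "anger")
})

test_that("the annotation rule is emotion-symmetric and scale-monotone", {
  set.seed(5)
  des <- c("anger", "disgust", "sadness", "tenderness")
  for (i in 1:20) {
    r <- round(runif(4, 0, 10), 1)
    names(r) <- des
    lab <- subjective_annotation(r)$emotion
    perm <- sample(4)
    r2 <- r[perm]
    names(r2) <- des
    lab2 <- subjective_annotation(r2)$emotion
    # permuting the scores permutes the winning emotion accordingly
    expect_equal(lab2, if (lab == "neutral") "neutral"
                 else des[which(des[perm] == lab)])
    # raising only the winner's score never changes the label away
    if (lab != "neutral") {
      r3 <- r
      r3[lab] <- min(10, r3[lab] + 1.5)
      expect_equal(subjective_annotation(r3)$emotion, lab)
    }
  }
})

test_that("the reference rating profile maps back to its own labels", {
  des <- des_rating_profile()
  ann <- subjective_annotation(des)
  expect_identical(ann$emotion, des$annotation)   # 4 of 4
})

test_that("hit rate and mean target rating count correctly", {
  obj <- c(rep("sadness", 10), rep("anger", 4))
  subj <- c(rep("sadness", 7), rep("neutral", 3), rep("anger", 4))
  hr <- hit_rate(obj, subj)
  expect_equal(unname(hr[["sadness"]]), 0.7)
  expect_equal(unname(hr[["anger"]]), 1)

  man <- data.frame(participant_id = "P01", video_id = c("v1", "v2"),
                    emotion = c("anger", "sadness"))
  rat <- data.frame(participant_id = "P01", video_id = c("v1", "v2"),
                    anger = c(8, 1), disgust = c(2, 1), sadness = c(1, 6),
                    tenderness = c(0, 0))
  mt <- mean_target_rating(rat, man)
  expect_equal(unname(mt[["anger"]]), 8)
  expect_equal(unname(mt[["sadness"]]), 6)
})

test_that("discreteness paired t-tests match hand computation", {
  # identical paired samples -> t = 0, p = 1 (zero-variance limit)
  rat <- data.frame(anger = c(5, 6, 7), disgust = c(5, 6, 7),
                    sadness = c(1, 1, 1), tenderness = c(0, 0, 0))
  expect_warning(
    d <- discreteness_test(rat, rep("anger", 3)), "zero-variance")
  row <- d[d$versus == "disgust", ]
  expect_equal(row$t, 0)
  expect_equal(row$p, 1)

  # constant positive difference -> +Inf limit
  rat2 <- data.frame(anger = c(5, 6, 7, 8), disgust = c(4, 5, 6, 7),
                     sadness = c(0, 0, 0, 0), tenderness = c(0, 0, 0, 0))
  expect_warning(d2 <- discreteness_test(rat2, rep("anger", 4)))
  expect_equal(d2[d2$versus == "disgust", "t"], Inf)

  # differences (2, 1, 3, 2, 2): t = 6.3246, df = 4
  x <- c(5, 4, 6, 5, 5)
  rat3 <- data.frame(anger = x + c(2, 1, 3, 2, 2), disgust = x,
                     sadness = rep(0, 5), tenderness = rep(0, 5))
  d3 <- suppressWarnings(discreteness_test(rat3, rep("anger", 5)))
  row3 <- d3[d3$versus == "disgust", ]
  expect_equal(row3$t, 2 / (sqrt(0.5) / sqrt(5)), tolerance = 1e-9)
  expect_equal(round(row3$t, 2), 6.32)
  expect_equal(row3$df, 4)
})

test_that("session annotation joins manifest and ratings coherently", {
  ses <- generate_session(2, seed = 31, duration_s = 4,
                          rating_noise_sd = 0)
  ann <- annotate_session(ses$ratings, ses$manifest)
  expect_equal(nrow(ann), 20)
  # noise-free ratings reproduce each video's own emotion label
  expect_identical(ann$emotion, ann$objective_emotion)
  expect_identical(ann$quadrant,
                   unname(c(anger = "HANV", disgust = "HANV",
                            sadness = "LANV", tenderness = "LAPV",
                            neutral = "MAMV")[ann$objective_emotion]))
})
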