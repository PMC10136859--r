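test_that("Bonferroni adjustment multiplies, caps and preserves order", {
  expect_equal(bonferroni(0.01, 3), 0.03)
  expect_equal(bonferroni(0.5, 3), 1)
  expect_equal(bonferroni(c(0.001, 0.02, 0.2), 3), c(0.003, 0.06, 0.6))
  p <- sort(runif(10))
  adj <- bonferroni(p, 10)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  expect_true(all(diff(adj) >= 0))
  expect_error(bonferroni(1.2, 2), "\\[0, 1\\]")
})

test_that("correlation pruning keeps the better-ranked member of a pair", {
  set.seed(2)
  n <- 200
  a <- rnorm(n)
  feats <- data.frame(fix_freq = a, blink_freq = a + rnorm(n, 0, 0.01),
                      pupil_mean = rnorm(n))
  ranking <- c(fix_freq = 0.001, blink_freq = 0.04, pupil_mean = 0.02)
  out <- prune_by_correlation(feats, names(ranking), ranking)
  expect_setequal(out$members, c("fix_freq", "pupil_mean"))

  # mutually uncorrelated candidates pass through unchanged
  feats2 <- data.frame(fix_freq = rnorm(n), blink_freq = rnorm(n),
                       pupil_mean = rnorm(n))
  out2 <- prune_by_correlation(feats2, names(ranking), ranking)
  expect_setequal(out2$members, names(ranking))

  # empty candidate set -> empty result
  expect_length(prune_by_correlation(feats, character(0), ranking)$members,
                0)
})

test_that("pruning output is a subset and shrinks as r_max drops", {
  set.seed(13)
  n <- 150
  base <- matrix(rnorm(n * 3), n, 3)
  feats <- as.data.frame(cbind(base,
                               base %*% matrix(rnorm(9, 0, 0.6), 3, 3) +
                                 matrix(rnorm(n * 3, 0, 0.5), n, 3)))
  names(feats) <- feature_schema()[1:6]
  ranking <- setNames(runif(6), names(feats))
  prev <- Inf
  for (rmax in c(0.9, 0.6, 0.3, 0.1)) {
    out <- prune_by_correlation(feats, names(feats), ranking, r_max = rmax)
    expect_true(all(out$members %in% names(feats)))
    expect_lte(length(out$members), prev)
    prev <- length(out$members)
  }
})

test_that("the packaged predictor sets have the documented sizes", {
  expect_length(feature_set("arousal")$members, 6)
  expect_length(feature_set("valence")$members, 8)
  expect_length(feature_set("combined")$members, 7)
  expect_length(feature_set("full")$members, 28)
  for (tg in c("arousal", "valence", "combined"))
    expect_true(all(feature_set(tg)$members %in% feature_schema()))
})

test_that("screening fixtures are well-formed", {
  for (tg in c("arousal", "valence", "quadrant")) {
    fx <- screening_fixture(tg)
    expect_true(all(fx$feature %in% feature_schema()))
    expect_true(all(fx$p_omnibus >= 0 & fx$p_omnibus <= 1))
    expect_true(all(as.matrix(fx[, -1]) >= 0 & as.matrix(fx[, -1]) <= 1))
    expect_true(all(fx$p_omnibus < 0.05))  # only significant features ship
  }
  # the fixture-derived candidate pools match the stated set sizes via
  # the packaged sets
  expect_true(all(feature_set("valence")$members %in%
                    c(screening_fixture("valence")$feature, "fix_freq",
                      "blink_freq")))
})

test_that("luminance confound check categorizes correlations", {
  tt <- seq(0, 60, by = 1 / 25)        # 25 fps frame clock
  v <- sin(tt / 3) + rnorm(length(tt), 0, 0.1)
  # pupil equal to V at the sample rate -> r = 1, strong
  pt <- seq(0, 60, by = 1 / 240)
  pv <- approx(tt, v, pt, rule = 2)$y
  lc <- luminance_check(pt, pv, tt, v)
  expect_gt(lc$r, 0.99)
  expect_equal(lc$category, "strong")

  # independent series -> |r| below the sampling bound
  set.seed(4)
  lc0 <- luminance_check(pt, rnorm(length(pt), 4, 0.2), tt,
                         rnorm(length(tt)))
  expect_lt(abs(lc0$r), 0.05)
  expect_equal(lc0$category, "very weak")

  # category boundaries
  expect_equal(correlation_category(0.15), "very weak")
  expect_equal(correlation_category(-0.3), "weak")
  expect_equal(correlation_category(0.45), "moderate")
  expect_equal(correlation_category(0.8), "strong")

  # zero-variance series -> r not available
  expect_true(is.na(luminance_check(pt, rep(4, length(pt)), tt, v)$r))
})

test_that("a generated luminance-coupled pupil is flagged, uncoupled is
           not", {
  tt <- seq(0, 20, by = 1 / 25)
  v <- as.numeric(scale(sin(tt / 2))) + rnorm(length(tt), 0, 0.2)
  g1 <- generate_recording(packaged_profile("MAMV"), duration_s = 20,
                           seed = 6, v_series = list(t = tt, v = v),
                           v_gain_mm = 0.4)
  lc1 <- luminance_check(g1$recording$t, g1$recording$pupil_mm, tt, v)
  expect_gt(abs(lc1$r), 0.4)
  g0 <- generate_recording(packaged_profile("MAMV"), duration_s = 20,
                           seed = 6)
  lc0 <- luminance_check(g0$recording$t, g0$recording$pupil_mm, tt, v)
  expect_lt(abs(lc0$r), 0.3)
})

test_that("the mixed model reduces to raw class means in balanced
           degenerate data", {
  set.seed(17)
  d <- expand.grid(participant = sprintf("P%02d", 1:12),
                   class = c("LA", "MA", "HA"), rep = 1:4)
  d$y <- rnorm(nrow(d))          # no participant effect at all
  res <- suppressWarnings(
    fit_feature_mlm(d$y, d$class, d$participant, posthoc = TRUE))
  raw <- tapply(d$y, d$class, mean)
  got <- setNames(res$class_means$mean, res$class_means$class)
  expect_equal(unname(got[names(raw)]), as.vector(raw), tolerance = 1e-6)
  expect_true(all(res$pairwise$p_adjusted >= res$pairwise$p_raw - 1e-12))
  expect_true(all(res$pairwise$p_adjusted <= 1))
})

test_that("the mixed model detects a one-within-SD class shift", {
  set.seed(23)
  d <- expand.grid(participant = sprintf("P%02d", 1:48), rep = 1:5)
  d$class <- sample(c("LA", "HA"), nrow(d), replace = TRUE)
  b <- rnorm(48, 0, 0.5)
  d$y <- b[as.integer(factor(d$participant))] +
    (d$class == "HA") * 1 + rnorm(nrow(d))
  res <- fit_feature_mlm(d$y, d$class, d$participant, posthoc = FALSE)
  expect_false(res$singular)
  expect_lt(res$p_omnibus, 0.05)
})
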