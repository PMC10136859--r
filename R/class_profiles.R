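#' Generator profile for one affect class
#'
#' Bundles the target statistics and distributional assumptions that the
#' synthetic recording generator reproduces for one arousal/valence class:
#' fixation-duration distribution (lognormal, left-truncated just above the
#' detector's minimum fixation duration, parameterized by target median and
#' CV), saccade-amplitude distribution (lognormal median/CV), a main
#' sequence linking amplitude to peak velocity, a blink rate and duration
#' distribution, and the pupil baseline mean/CV. The constructor calibrates
#' the truncated-lognormal location parameter numerically so the median of
#' the emitted (truncated) durations equals the stated target, and
#' precomputes the per-cycle blink probability that realizes the stated
#' blink rate in the alternating fixation/saccade/blink process.
#'
#' @param label Class label (e.g. `"HA"`, `"NV"`, `"HANV"`).
#' @param fix_dur_median_ms,fix_dur_cv Fixation duration target median (ms)
#'   and coefficient of variation.
#' @param sac_amp_median_deg,sac_amp_cv Saccade amplitude target median
#'   (deg) and CV.
#' @param sac_pvel_mean_deg_s Target mean peak saccade velocity (deg/s);
#'   sets the main-sequence scale.
#' @param blink_rate_hz Blink rate (blinks/s).
#' @param blink_dur_mean_ms,blink_dur_cv Blink duration mean (ms) and CV.
#' @param pupil_mean_mm,pupil_cv Pupil diameter baseline mean (mm) and CV.
#' @param pupil_baseline_sd_mm Between-recording SD of the (zero-mean)
#'   pupil baseline jitter.
#' @param main_seq_b Main-sequence saturation constant (deg): peak velocity
#'   `= a * (1 - exp(-amplitude / b))`, with `a` solved from the target
#'   peak velocity at the median amplitude.
#' @param emotions Emotions whose DES rating rows belong to this class
#'   (used by the session generator).
#' @param min_fix_s Lower truncation bound of fixation durations (s);
#'   must clear the detector's 55 ms minimum after sample rounding.
#' @return A `class_profile` object.
#' @export
class_profile <- function(label,
                          fix_dur_median_ms, fix_dur_cv,
                          sac_amp_median_deg, sac_amp_cv,
                          sac_pvel_mean_deg_s,
                          blink_rate_hz, blink_dur_mean_ms,
                          blink_dur_cv = 0.25,
                          pupil_mean_mm, pupil_cv,
                          pupil_baseline_sd_mm = 0.15,
                          main_seq_b = 7,
                          emotions = "neutral",
                          min_fix_s = 0.057) {
  stopifnot(fix_dur_median_ms > 0, sac_amp_median_deg > 0,
            blink_rate_hz >= 0, pupil_mean_mm > 0)
  fix_sdlog <- sqrt(log(1 + fix_dur_cv^2))
  amp_sdlog <- sqrt(log(1 + sac_amp_cv^2))
  blink_sdlog <- sqrt(log(1 + blink_dur_cv^2))

  fix_meanlog <- calibrate_trunc_lnorm_median(fix_dur_median_ms / 1000,
                                              fix_sdlog, min_fix_s)
  amp_meanlog <- log(sac_amp_median_deg)   # truncation at 2 deg is ~massless
  blink_meanlog <- log(blink_dur_mean_ms / 1000) - blink_sdlog^2 / 2

  main_seq_a <- sac_pvel_mean_deg_s /
    (1 - exp(-sac_amp_median_deg / main_seq_b))

  # expected event durations, for the rate-preserving blink probability
  mu_fix <- trunc_lnorm_mean(fix_meanlog, fix_sdlog, min_fix_s)
  qs <- stats::qlnorm(stats::ppoints(2001), amp_meanlog, amp_sdlog)
  pv <- main_seq_a * (1 - exp(-qs / main_seq_b))
  mu_sac <- mean(qs / (0.75 * pv))
  mu_blink <- blink_dur_mean_ms / 1000
  p_blink <- if (blink_rate_hz > 0) {
    blink_rate_hz * (mu_fix + mu_sac) / (1 - blink_rate_hz * mu_blink)
  } else 0
  if (p_blink < 0 || p_blink > 1)
    stop("blink rate/duration combination is infeasible for the ",
         "alternating event process")

  structure(list(
    label = label,
    fix_dur_median_ms = fix_dur_median_ms, fix_dur_cv = fix_dur_cv,
    sac_amp_median_deg = sac_amp_median_deg, sac_amp_cv = sac_amp_cv,
    sac_pvel_mean_deg_s = sac_pvel_mean_deg_s,
    blink_rate_hz = blink_rate_hz,
    blink_dur_mean_ms = blink_dur_mean_ms, blink_dur_cv = blink_dur_cv,
    pupil_mean_mm = pupil_mean_mm, pupil_cv = pupil_cv,
    pupil_baseline_sd_mm = pupil_baseline_sd_mm,
    main_seq_a = main_seq_a, main_seq_b = main_seq_b,
    emotions = emotions, min_fix_s = min_fix_s,
    fix_meanlog = fix_meanlog, fix_sdlog = fix_sdlog,
    amp_meanlog = amp_meanlog, amp_sdlog = amp_sdlog,
    blink_meanlog = blink_meanlog, blink_sdlog = blink_sdlog,
    mu_fix_s = mu_fix, mu_sac_s = mu_sac, mu_blink_s = mu_blink,
    p_blink = p_blink),
    class = "class_profile")
}

#' @export
print.class_profile <- function(x, ...) {
  cat(sprintf(paste0(
    "<class_profile> %s: fix %.1f ms (cv %.2f), amp %.2f deg (cv %.2f), ",
    "peak vel %.0f deg/s, blink %.2f /s x %.0f ms, pupil %.2f mm (cv %.3f)\n"),
    x$label, x$fix_dur_median_ms, x$fix_dur_cv, x$sac_amp_median_deg,
    x$sac_amp_cv, x$sac_pvel_mean_deg_s, x$blink_rate_hz,
    x$blink_dur_mean_ms, x$pupil_mean_mm, x$pupil_cv))
  invisible(x)
}

# Median of a lognormal left-truncated at L.
trunc_lnorm_median <- function(meanlog, sdlog, L) {
  p0 <- stats::plnorm(L, meanlog, sdlog)
  stats::qlnorm(p0 + 0.5 * (1 - p0), meanlog, sdlog)
}

# Mean of a lognormal left-truncated at L.
trunc_lnorm_mean <- function(meanlog, sdlog, L) {
  z <- (log(L) - meanlog) / sdlog
  exp(meanlog + sdlog^2 / 2) * stats::pnorm(sdlog - z) / stats::pnorm(-z)
}

# Solve for meanlog so the truncated median equals the target.
calibrate_trunc_lnorm_median <- function(target, sdlog, L) {
  if (target <= L) stop("target median must exceed the truncation bound")
  f <- function(ml) trunc_lnorm_median(ml, sdlog, L) - target
  stats::uniroot(f, lower = log(target) - 2, upper = log(target) + 1e-6,
                 tol = 1e-12)$root
}

# Inverse-CDF draw from the left-truncated lognormal.
rtrunc_lnorm <- function(n, meanlog, sdlog, L) {
  p0 <- stats::plnorm(L, meanlog, sdlog)
  stats::qlnorm(p0 + stats::runif(n) * (1 - p0), meanlog, sdlog)
}

.profile_table <- function() {
  # per-class targets: fixation duration median/CV, saccade amplitude
  # median/CV, mean peak velocity, blink rate/duration, pupil mean/CV
  utils::read.csv(text =
"label,fix_med,fix_cv,amp_med,amp_cv,pvel,brate,bdur,pmean,pcv
LA,314.50,0.87,14.01,0.18,299.83,0.21,215.32,3.85,0.067
MA,306.94,0.89,13.88,0.20,320.39,0.27,214.88,3.74,0.076
HA,295.52,0.87,14.00,0.18,310.35,0.22,220.45,3.95,0.076
NV,303.62,0.87,14.08,0.18,308.00,0.23,218.83,3.87,0.073
MV,307.48,0.89,13.89,0.20,320.27,0.27,214.79,3.74,0.076
PV,310.83,0.89,13.77,0.18,295.27,0.19,214.61,4.00,0.067",
    stringsAsFactors = FALSE)
}

#' Packaged class profiles
#'
#' Generator profiles for the three arousal levels (LA/MA/HA), the three
#' valence levels (NV/MV/PV) and the four occupied arousal-valence
#' quadrants (HANV/LANV/LAPV/MAMV). Level profiles carry the per-class
#' estimated feature means of the study population; each quadrant profile
#' averages the targets of its arousal and valence levels and carries the
#' DES rating rows of its member emotions.
#'
#' @param label One of `"LA"`, `"MA"`, `"HA"`, `"NV"`, `"MV"`, `"PV"`,
#'   `"HANV"`, `"LANV"`, `"LAPV"`, `"MAMV"`.
#' @return A [class_profile()].
#' @export
packaged_profile <- function(label = c("LA", "MA", "HA", "NV", "MV", "PV",
                                       "HANV", "LANV", "LAPV", "MAMV")) {
  label <- match.arg(label)
  tab <- .profile_table()
  rownames(tab) <- tab$label
  quadrants <- list(HANV = c("HA", "NV"), LANV = c("LA", "NV"),
                    LAPV = c("LA", "PV"), MAMV = c("MA", "MV"))
  emo <- list(HANV = c("anger", "disgust"), LANV = "sadness",
              LAPV = "tenderness", MAMV = "neutral",
              LA = c("sadness", "tenderness"), MA = "neutral",
              HA = c("anger", "disgust"),
              NV = c("anger", "disgust", "sadness"), MV = "neutral",
              PV = "tenderness")
  row <- if (label %in% names(quadrants)) {
    colMeans(tab[quadrants[[label]], -1])
  } else {
    unlist(tab[label, -1])
  }
  class_profile(label,
                fix_dur_median_ms = row[["fix_med"]],
                fix_dur_cv = row[["fix_cv"]],
                sac_amp_median_deg = row[["amp_med"]],
                sac_amp_cv = row[["amp_cv"]],
                sac_pvel_mean_deg_s = row[["pvel"]],
                blink_rate_hz = row[["brate"]],
                blink_dur_mean_ms = row[["bdur"]],
                pupil_mean_mm = row[["pmean"]],
                pupil_cv = row[["pcv"]],
                emotions = emo[[label]])
}
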