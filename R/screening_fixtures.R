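#' Versioned feature-screening fixtures
#'
#' Mixed-linear-model screening outcomes (omnibus p-value per feature and
#' Bonferroni-adjusted pairwise p-values per class pair) obtained on the
#' study recordings, shipped as fixtures so that feature selection and the
#' classifier presets can run without access to the original dataset. Only
#' features whose omnibus test reached p < 0.05 are listed.
#'
#' @param target `"arousal"` (classes LA/MA/HA), `"valence"` (NV/MV/PV) or
#'   `"quadrant"` (the four occupied arousal-valence classes).
#' @return Data.frame with `feature`, `p_omnibus` and one adjusted-p column
#'   per class pair.
#' @export
screening_fixture <- function(target = c("arousal", "valence", "quadrant")) {
  target <- match.arg(target)
  switch(target, arousal = .fixture_arousal(), valence = .fixture_valence(),
         quadrant = .fixture_quadrant())
}

.fixture_arousal <- function() {
  df <- utils::read.csv(text = "feature,p_omnibus,LA_MA,LA_HA,MA_HA
fix_freq,0.009,1.000,0.030,0.027
fix_dur_median,0.005,0.744,0.003,0.230
fix_dur_skew,0.043,0.700,0.478,0.038
fix_dur_kurt,0.007,0.290,0.328,0.005
sac_freq,0.001,0.604,0.000,0.095
sac_amp_cv,0.043,0.048,1.000,0.139
sac_vel_cv,0.014,0.065,0.023,1.000
sac_vel_skew,0.045,0.043,0.367,0.818
sac_pvel_cv,0.019,0.132,0.023,1.000
sac_dur_median,0.000,0.000,0.257,0.029
sac_dur_cv,0.004,0.597,0.089,0.004
sac_dur_skew,0.005,0.830,0.076,0.005
sac_dur_kurt,0.021,1.000,0.060,0.045
blink_freq,0.001,0.001,1.000,0.004
pupil_mean,0.000,0.080,0.093,0.000
pupil_cv,0.008,0.042,0.014,1.000", stringsAsFactors = FALSE)
  df
}

.fixture_valence <- function() {
  utils::read.csv(text = "feature,p_omnibus,NV_MV,NV_PV,MV_PV
fix_freq,0.045,0.120,0.187,1.000
fix_dur_kurt,0.020,0.015,1.000,0.419
sac_amp_median,0.000,0.047,0.001,0.701
sac_amp_cv,0.047,0.063,1.000,0.128
sac_vel_skew,0.011,0.535,0.065,0.009
sac_pvel_skew,0.023,0.619,0.116,0.019
sac_dur_median,0.000,0.004,0.400,0.001
sac_dur_cv,0.003,0.007,0.074,1.000
sac_dur_skew,0.031,0.029,0.751,0.950
blink_freq,0.000,0.005,0.068,0.000
pupil_mean,0.000,0.013,0.018,0.000
pupil_kurt,0.010,1.000,0.013,0.021", stringsAsFactors = FALSE)
}

.fixture_quadrant <- function() {
  utils::read.csv(text = paste0(
    "feature,p_omnibus,LANV_MAMV,LANV_LAPV,LANV_HANV,",
    "MAMV_LAPV,MAMV_HANV,LAPV_HANV\n",
    "fix_freq,0.019,1.000,1.000,0.483,1.000,0.046,0.086
fix_dur_median,0.012,1.000,1.000,0.014,1.000,0.353,0.176
fix_dur_kurt,0.019,0.819,1.000,1.000,1.000,0.010,1.000
sac_freq,0.002,1.000,1.000,0.003,1.000,0.182,0.034
sac_amp_median,0.000,0.005,0.000,0.078,1.000,1.000,0.081
sac_vel_cv,0.017,0.052,1.000,0.022,1.000,1.000,0.820
sac_vel_skew,0.021,0.918,0.559,1.000,0.012,1.000,0.133
sac_pvel_cv,0.019,0.083,1.000,0.017,1.000,1.000,0.907
sac_pvel_skew,0.041,0.849,1.000,1.000,0.030,1.000,0.208
sac_dur_median,0.001,0.008,1.000,1.000,0.001,0.059,0.451
sac_dur_cv,0.004,0.440,1.000,1.000,1.000,0.007,0.068
sac_dur_skew,0.015,1.000,1.000,0.279,1.000,0.012,0.496
blink_freq,0.000,0.299,0.074,1.000,0.000,0.007,0.352
pupil_mean,0.000,1.000,0.000,0.000,0.000,0.000,1.000
pupil_cv,0.025,0.212,1.000,0.102,0.297,1.000,0.148
pupil_skew,0.037,0.961,0.022,0.680,0.470,1.000,0.540
pupil_kurt,0.020,1.000,0.043,1.000,0.036,1.000,0.064"),
    stringsAsFactors = FALSE)
}

#' Reference DES rating profile per subjective annotation
#'
#' Mean differential-emotion-scale rating vectors observed for recordings
#' grouped by their subjective annotation; each row satisfies the
#' annotation rule for its own emotion. Used as the rating targets of the
#' synthetic session generator.
#'
#' @return Data.frame with `annotation` and the four DES rating columns.
#' @export
des_rating_profile <- function() {
  utils::read.csv(text = "annotation,anger,disgust,sadness,tenderness
anger,7.7,4.5,5.7,0.2
disgust,4.2,8.4,4.0,0.1
sadness,3.8,3.3,7.5,0.1
tenderness,0.4,0.1,0.1,6.4", stringsAsFactors = FALSE)
}
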