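---
title: "Estimating arousal and valence from eye-tracking features: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating arousal and valence from eye-tracking features: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oculaff)
```

## The problem

When people watch emotionally evocative film clips, their oculomotor
behaviour changes: pupil diameter, blink rate, fixation and saccade
dynamics all respond to emotional arousal (how exciting vs calming a state
is) and valence (how pleasant it is). `oculaff` implements a complete
pipeline from raw eye-tracker sample streams to arousal/valence
classification:

1. **Recording model and validity screening** (`raw_recording`,
   `validity_filter`): per-recording streams of timestamps, normalized
   gaze, pupil diameter (mm) and detection confidence, plus tracker blink
   intervals. Recordings are excluded when the eyes were closed for more
   than 10% of the clip, when gaze was off screen for more than 20% of it
   (a mind-wandering proxy), or when playback was aborted.
2. **Gaze preprocessing** (`to_visual_angle`, `angular_velocity`,
   `five_tap_velocity_filter`): normalized coordinates are projected onto
   the physical display and converted to degrees of visual angle; angular
   speed is the exact great-circle angle between consecutive 3-D gaze
   directions divided by the time step; a 5-tap filter denoises the speed
   series.
3. **Event detection** (`ivt_segment`, `assemble_blinks`): the
   velocity-threshold (I-VT) algorithm labels every sample pair fixation
   (speed strictly below 45 deg/s) or saccade (at/above), collapses
   fixation runs, discards groups shorter than 55 ms, and summarizes
   saccade runs by endpoint amplitude and mean/peak velocity. Blinks come
   from tracker intervals or, failing that, low-confidence runs.
4. **Feature extraction** (`extract_features`): 28 features per recording
   — frequencies, and median-or-mean/CV/skewness/kurtosis summaries of
   fixation duration, saccade duration/amplitude/velocity/peak velocity,
   blink duration, and pupil diameter.
5. **Affect annotation** (`subjective_annotation`): four
   differential-emotion-scale ratings (anger, disgust, sadness,
   tenderness; 0–10) map to an emotion label when the top rating is at
   least 4 and leads by at least 1 point, else neutral; emotions map to
   fixed circumplex positions (anger/disgust HANV, sadness LANV,
   tenderness LAPV, neutral MAMV).
6. **Screening and selection** (`fit_feature_mlm`, `prune_by_correlation`):
   per-feature linear mixed models with the class as fixed effect and a
   participant random intercept (repeated measures make plain ANOVA
   invalid), Bonferroni post hoc contrasts, then correlation pruning
   (|r| > 0.3) that keeps the better-screening member of each correlated
   pair. The packaged predictor sets have 6 (arousal), 8 (valence) and 7
   (combined) features.
7. **Classification** (`train_eval`): deep multilayer perceptrons — input
   N ∈ {6,7,8,28}, 2–3 ReLU hidden layers of 8–256 units with dropout
   0.25, sigmoid/softmax heads — trained with Adam on (categorical) binary
   cross-entropy; architectures are compared on an 80/20 split and the
   reported metrics (accuracy, macro f1, AUC) come from stratified 10-fold
   cross-validation.

A synthetic recording generator (`generate_recording`,
`generate_session`) makes every stage testable without the original
recordings.

## The synthetic generator

The generator emits an alternating renewal process of fixations, optional
blinks and saccades at 240 Hz, with exact ground truth. Design choices:

* **Fixation durations** are lognormal (right-skewed, heavy-tailed, as the
  positive skewness/kurtosis of observed duration distributions implies),
  left-truncated at 57 ms so every emitted fixation clears the detector's
  55 ms minimum after sample rounding. The location parameter is
  calibrated numerically at profile construction so that the *median of
  the emitted durations* equals the class target — calibration to the
  published class statistics is the generator's contract, done
  analytically, once, at construction.
* **Fixation jitter** is a mean-reverting AR(1) miniature motion whose
  per-step displacement is hard-bounded below 35 deg/s, so fixation
  samples can never cross the 45 deg/s threshold (a construction
  guarantee, verified by a property test).
* **Saccades** move along a great circle to an on-screen target at the
  drawn amplitude (lognormal median/CV per class). The velocity profile is
  a discrete trapezoid whose every sample-pair displacement is floored at
  60 deg/s; peak velocity follows a saturating main sequence
  `v_peak = a (1 − exp(−A/b))` with `b = 7` deg and `a` set from the class
  peak-velocity target. Consequently detected boundaries and endpoint
  amplitudes reproduce the ground truth exactly. The published per-class
  saccade amplitude (~14 deg), mean velocity (~230 deg/s) and duration
  (~22 ms) summaries are mutually incompatible with ballistic kinematics
  (14 deg at 230 deg/s takes ~61 ms), so the generator honours amplitude
  and velocity and lets duration emerge (~60 ms) — a deliberate modeling
  choice.
* **Blinks** are inserted between a fixation and the following saccade
  with probability `p = λ(μ_fix + μ_sac) / (1 − λ μ_blink)`, which makes
  the long-run blink rate equal the class target λ while keeping blinks
  from splitting fixations. Blink interiors drop confidence below the
  blink threshold and blank the pupil; the tracker-style blink table
  carries the exact intervals.
* **Pupil diameter** is baseline + per-recording zero-mean baseline jitter
  (SD 0.15 mm) + slow AR(1) drift (5 s correlation time) + white noise,
  with total variation matching the class CV. An optional toggle couples a
  supplied per-frame brightness (V) series into the pupil, solely to
  exercise the luminance confound check.
* **Class profiles** carry the published per-class feature means: the six
  arousal/valence level profiles directly, and the four quadrant profiles
  as the average of their arousal- and valence-level targets. Session
  generation draws participant-level random offsets (additive pupil
  baseline, log-scale fixation/blink/amplitude factors) so repeated
  recordings of one participant are dependent, as the mixed-model
  screening assumes, and draws DES ratings around each emotion's reference
  rating row.

What the generator does **not** emulate: smooth pursuit (film stimuli
elicit it; I-VT misclassifies slow pursuit as fixation), glissades and
post-saccadic oscillations, corneal-reflection dropouts other than blinks,
luminance-driven pupil dynamics (beyond the test toggle), head motion, and
measurement noise on the pupil edge. Passing recovery tests therefore
demonstrates the pipeline's internal consistency — detector, features and
models faithfully recover what the data contain — not robustness to every
artifact of real recordings.

## Numerical and procedural choices

* **Velocity filter.** The 5-tap filter defaults to a running *median*:
  its purpose in this pipeline is to remove isolated one-sample velocity
  spikes, and a median does that while passing monotone ramps and plateaus
  — hence saccade on/offsets — unchanged. A uniform-kernel moving average
  (available via `method = "mean"`, kernel configurable) smears event
  boundaries by up to two samples and biases fixation-duration summaries;
  it is kept for comparison because some toolchains smooth rather than
  despike. Windows truncate at series edges and at masked (blink) samples.
* **Boundary conventions.** Fixation requires speed strictly below the
  threshold (equality is a saccade point). A run of k intervals spans
  k + 1 samples, so consecutive events share boundary samples and a
  fixation of k intervals lasts k/Fs. Blink-interval *interiors* are
  masked; the boundary samples are the last/first well-tracked samples and
  remain usable, which keeps post-blink saccade amplitudes unclipped.
  Discarded sub-55 ms fixation groups become unclassified gaps — they are
  not merged into saccades.
* **Summary statistics.** CV uses the n−1 standard deviation; skewness is
  Fisher–Pearson `m3/m2^1.5`; kurtosis defaults to excess (most stacks'
  default; the published tables do not disambiguate) with a raw option.
  Zero-variance samples get skewness 0 with a warning; empty event families
  yield NA features, never silent zeros. Frequencies divide by the full
  recording duration, not valid time.
* **Annotation rule.** "At least 1 point higher" is implemented as ≥ 1.0;
  ties at the top fail the rule and fall back to neutral. Ratings are
  accepted as reals in [0, 10] so group-mean vectors flow through the same
  rule.
* **Mixed models.** REML fits via `lme4`, omnibus p-values from
  `lmerTest`'s Satterthwaite F test, class means and pairwise contrasts
  via `emmeans` with Bonferroni adjustment (`min(1, p·k)`). A singular fit
  (zero random-intercept variance) falls back to a fixed-effects linear
  model with a warning. A 500-replicate null simulation holds the type-I
  error within [0.03, 0.07] at α = 0.05.
* **Correlation pruning.** When more than two candidates inter-correlate,
  the worst-ranked member over all super-threshold pairs is removed and
  correlations are recomputed — deterministic for a fixed ranking. "Better
  distinguishing" is operationalized as the smaller screening p-value, and
  `r > 0.3` as |r| > 0.3.
* **Classifiers.** Multiclass heads use categorical cross-entropy (the
  binary loss's generalization). Multiclass AUC is macro one-vs-rest.
  Features are z-scored inside each CV fold, with missing values imputed
  by the training fold's median (no missingness indicator: it would change
  the input size out of the N ∈ {6,7,8,28} family). Training uses Adam
  (lr 1e-3), 200 epochs, batch 32, early stopping with patience 20 on an
  internal 10% validation split; all budgets are arguments. Architecture
  search fixes the winning layout on an 80/20 split first; 10-fold CV then
  produces the reported metrics — the search is not re-run per fold.
* **Determinism.** Every stochastic step (generation, fold assignment,
  initialization, dropout, batching) flows from the caller's seed; same
  seed, data and spec give identical reports.

## Problem sizes used by the test suite

Parameter-recovery checks use 200 recordings of 60 s at 240 Hz per class
— enough for Monte-Carlo standard errors of ~0.01 mm (pupil), ~2 ms
(fixation-duration median), ~0.004 /s (blink rate) and ~0.02 deg
(amplitude median) — with a two-standard-error acceptance band, which an
unbiased generator meets with ~95% probability per quantity. Mixed-model
calibration uses 500 null replicates of 30 participants × 6 recordings.
Classifier property checks use 100–200 observations per class with
reduced training budgets; these sizes were chosen as the smallest at which
the checked contrasts (chance vs ceiling vs monotone ordering) are
decisively separated from Monte-Carlo noise.

## Known limitations

* I-VT with a fixed 45 deg/s threshold is blind to smooth pursuit and
  conflates it with fixation; dispersion- or HMM-based detectors are out
  of scope.
* The luminance check verifies the confound is weak; it does not correct
  pupil size for luminance.
* The quadrant profiles average level targets; real quadrant-conditional
  feature distributions need not decompose additively.
* Published headline classification accuracies were obtained on the real
  recordings; the synthetic generator reproduces class-conditional
  summary statistics, not the full covariance structure of real data, so
  classifier accuracies on synthetic sessions are comparable in kind but
  not in value.
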