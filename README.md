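# oculaff

Estimation of emotional arousal and valence from eye-tracking features.

## The problem

Oculomotor behaviour carries affective information: pupil diameter, blink
rate, and fixation/saccade dynamics all respond to how exciting (arousal)
and how pleasant (valence) an emotional state is. `oculaff` is a complete,
tested pipeline for studies in which participants watch emotion-evoking
video clips while a 240 Hz eye tracker records gaze, pupil and blinks, and
then rate the four emotions of a differential emotions scale (DES: anger,
disgust, sadness, tenderness; 0–10):

* **Recording I/O and validity screening** — CSV sample streams
  (`timestamp_s, gaze_x_norm, gaze_y_norm, pupil_mm, confidence`), blink
  and manifest tables; recordings are excluded when eyes were closed
  > 10% of the clip, gaze was off screen > 20% of it, or playback was
  aborted.
* **Oculomotor event detection** — gaze is converted to degrees of visual
  angle (`θ = atan(offset/distance)`), angular speed is denoised with a
  5-tap velocity filter, and the I-VT rule segments events: sample pairs
  with speed `v < 45°/s` are fixation points, `v ≥ 45°/s` saccade points;
  fixation groups shorter than 55 ms are discarded.
* **Feature extraction** — the 28-dimensional feature vector per
  recording: frequencies plus {median-or-mean, CV, skewness, kurtosis}
  summaries of fixation duration, saccade duration/amplitude/velocity/
  peak velocity, blink duration and pupil diameter.
* **Affect annotation** — an emotion is the subjective annotation iff its
  rating is ≥ 4 and leads every other rating by ≥ 1 point, else neutral;
  emotions map to circumplex classes (anger/disgust → HANV, sadness →
  LANV, tenderness → LAPV, neutral → MAMV), giving arousal levels
  LA/MA/HA and valence levels NV/MV/PV.
* **Statistical screening and feature selection** — per-feature linear
  mixed models `feature ~ class + (1 | participant)` (REML, Satterthwaite
  omnibus test, Bonferroni post hoc) and correlation pruning (|r| > 0.3
  keeps the better-screening member), yielding packaged predictor sets of
  6 (arousal), 8 (valence) and 7 (combined) features.
* **Classification** — deep multilayer perceptrons with N ∈ {6,7,8,28}
  inputs, 2–3 ReLU hidden layers (8–256 units, dropout 0.25), sigmoid or
  softmax heads, Adam on (categorical) binary cross-entropy; stratified
  10-fold cross-validated AUC/f1/accuracy, with presets for all published
  task layouts (e.g. `NV+MV_vs_PV` with hidden sizes 64, 16).
* **Synthetic data** — a generator of realistic 240 Hz recordings
  (lognormal fixation durations, main-sequence saccades traced on great
  circles, boundary blinks, drifting pupil) with exact ground truth and
  packaged per-class profiles, so the whole pipeline runs and is tested
  without the original dataset. A loader (`load_esee_d`) maps a local
  copy of the deposited archive (Zenodo accession 10.5281/zenodo.5775674)
  into the same model.

## Worked example

```r
library(oculaff)

g <- generate_recording(packaged_profile("HANV"), duration_s = 30, seed = 1)
rec <- g$recording
rec
#> <raw_recording> participant synthetic, video synthetic: 7282 samples @ 240 Hz, 30.3 s, 5 blink interval(s)

events <- detect_events(rec)
events
#> <oculomotor_events> 30.3 s: 67 fixation(s), 66 saccade(s), 5 blink(s)

fv <- extract_features(events, rec)
round(unclass(fv)[c("fix_freq", "fix_dur_median", "sac_amp_median",
                    "blink_freq", "pupil_mean")], 3)
#>       fix_freq fix_dur_median sac_amp_median     blink_freq     pupil_mean
#>          2.208        295.833         14.099          0.165          3.915

subjective_annotation(c(anger = 7.7, disgust = 4.5, sadness = 5.7,
                        tenderness = 0.2))
#>   emotion arousal valence quadrant
#> 1   anger      HA      NV     HANV
```

The recording behaves like a high-arousal/negative-valence viewing: ~2.2
fixations/s with a ~296 ms median duration, ~14° saccades, 0.165 blinks/s,
and a 3.92 mm mean pupil diameter. The rating vector (anger 7.7 leading
sadness 5.7 by 2 points) annotates as anger, hence HANV.

From a full synthetic session, screening and classification run as:

```r
ses   <- generate_session(8, seed = 1, duration_s = 30)
feats <- extract_features_batch(ses$recordings)
ann   <- annotate_session(ses$ratings, ses$manifest)
scr   <- screen_features(feats, ann$arousal)            # mixed models
rep   <- train_eval(feats, ann, "HA_vs_LA", seed = 1)   # 10-fold CV
```

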