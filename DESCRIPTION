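Package: oculaff
Title: Arousal and Valence Estimation from Eye-Tracking Features
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An analysis pipeline for estimating emotional arousal and
    valence from eye-tracking recordings of people watching emotion-evoking
    videos. Converts raw gaze sample streams (normalized gaze coordinates,
    pupil diameter, detection confidence) into oculomotor events with a
    velocity-threshold (I-VT) fixation/saccade detector, extracts a
    28-dimensional eye and gaze feature vector, derives affect labels from
    differential-emotion-scale self ratings, screens features with
    participant-random-intercept mixed linear models and correlation
    pruning, and classifies arousal/valence levels with a family of deep
    multilayer perceptrons. A synthetic recording generator with known
    ground truth makes every stage testable without access to the original
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    emmeans,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
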