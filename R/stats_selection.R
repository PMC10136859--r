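#' Mixed-linear-model screening of one feature
#'
#' Fits a linear model with the class factor (arousal level, valence level
#' or quadrant) as the fixed effect and a participant random intercept,
#' by REML through \pkg{lme4}/\pkg{lmerTest}. Repeated recordings of the
#' same participant make observations dependent, which is why a plain ANOVA
#' is not appropriate here. Returns the omnibus fixed-effect p-value
#' (Satterthwaite F test) and, optionally, estimated marginal class means
#' with standard errors and Bonferroni-adjusted pairwise comparisons via
#' \pkg{emmeans}. A singular fit with zero random-intercept variance falls
#' back to a fixed-effects linear model with a warning.
#'
#' @param values Numeric feature values, one per recording.
#' @param classes Class labels (factor or character).
#' @param participants Participant identifiers.
#' @param posthoc Compute class means and Bonferroni pairwise p-values
#'   (default TRUE; disable for speed in large simulation loops).
#' @return An `mlm_result` list: `p_omnibus`, `class_means` (data.frame
#'   with `class`, `mean`, `se`) and `pairwise` (data.frame with
#'   `contrast`, `p_raw`, `p_adjusted`), the latter two NULL when
#'   `posthoc = FALSE`, plus `singular`.
#' @export
fit_feature_mlm <- function(values, classes, participants, posthoc = TRUE) {
  d <- data.frame(y = as.numeric(values), class = factor(classes),
                  participant = factor(participants))
  d <- d[stats::complete.cases(d), ]
  if (nlevels(droplevels(d$class)) < 2)
    stop("need at least 2 classes")
  if (nlevels(droplevels(d$participant)) < 2)
    stop("need at least 2 participants")
  d$class <- droplevels(d$class)

  fit <- suppressMessages(
    lmerTest::lmer(y ~ class + (1 | participant), data = d, REML = TRUE))
  singular <- lme4::isSingular(fit, tol = 1e-5)
  if (singular) {
    warning("random-intercept variance is ~0; falling back to a ",
            "fixed-effects linear model")
    lmfit <- stats::lm(y ~ class, data = d)
    p_omni <- stats::anova(lmfit)[["Pr(>F)"]][1]
    model <- lmfit
  } else {
    an <- stats::anova(fit)  # lmerTest Satterthwaite F test
    p_omni <- an[["Pr(>F)"]][1]
    model <- fit
  }

  class_means <- pairwise <- NULL
  if (posthoc) {
    emm <- emmeans::emmeans(model, "class")
    es <- as.data.frame(emm)
    class_means <- data.frame(class = as.character(es$class),
                              mean = es$emmean, se = es$SE)
    pr_raw <- as.data.frame(emmeans::contrast(emm, "pairwise",
                                              adjust = "none"))
    k <- nrow(pr_raw)
    pairwise <- data.frame(contrast = as.character(pr_raw$contrast),
                           p_raw = pr_raw$p.value,
                           p_adjusted = bonferroni(pr_raw$p.value, k))
  }
  structure(list(p_omnibus = p_omni, class_means = class_means,
                 pairwise = pairwise, singular = singular),
            class = "mlm_result")
}

#' Screen every feature with the mixed linear model
#'
#' @param features Feature data.frame (columns of [feature_schema()] plus
#'   `participant_id`).
#' @param classes Class labels per row.
#' @param feature_names Features to screen (default: all schema columns
#'   present).
#' @param posthoc Passed to [fit_feature_mlm()].
#' @return Data.frame `feature`, `p_omnibus`, `singular`, ordered as
#'   screened, with the per-feature `mlm_result`s in attribute `"fits"`.
#' @export
screen_features <- function(features, classes,
                            feature_names = intersect(feature_schema(),
                                                      names(features)),
                            posthoc = FALSE) {
  fits <- lapply(feature_names, function(f)
    suppressWarnings(fit_feature_mlm(features[[f]], classes,
                                     features$participant_id, posthoc)))
  out <- data.frame(feature = feature_names,
                    p_omnibus = vapply(fits, `[[`, 0, "p_omnibus"),
                    singular = vapply(fits, `[[`, FALSE, "singular"))
  attr(out, "fits") <- stats::setNames(fits, feature_names)
  out
}

#' Bonferroni adjustment
#'
#' @param pvals Raw p-values in \[0, 1\].
#' @param k Number of comparisons (default `length(pvals)`).
#' @return `min(1, p * k)` elementwise.
#' @export
bonferroni <- function(pvals, k = length(pvals)) {
  if (k < 1) stop("k must be >= 1")
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  pmin(1, pvals * k)
}

#' Correlation-pruning feature selection
#'
#' Iterates over candidate feature pairs whose absolute Pearson correlation
#' exceeds `r_max` and greedily drops the member ranked worse by the
#' supplied effect ranking (smaller screening p-value = better), repeating
#' until no super-threshold pair survives. Deterministic for a fixed
#' ranking; the output is always a subset of the candidates.
#'
#' @param features Feature data.frame.
#' @param candidates Candidate feature names (must be columns).
#' @param ranking Named numeric vector of screening p-values (lower is
#'   better), covering the candidates.
#' @param r_max Correlation threshold (default 0.3, absolute value).
#' @param target Label stored on the returned set.
#' @return A `feature_set_spec`: list with `target` and `members`.
#' @export
prune_by_correlation <- function(features, candidates, ranking,
                                 r_max = 0.3, target = "custom") {
  if (length(candidates) == 0)
    return(feature_set_spec(target, character(0)))
  stopifnot(all(candidates %in% names(features)),
            all(candidates %in% names(ranking)))
  keep <- candidates
  repeat {
    if (length(keep) < 2) break
    cm <- suppressWarnings(
      stats::cor(features[, keep], use = "pairwise.complete.obs"))
    diag(cm) <- 0
    cm[is.na(cm)] <- 0
    if (max(abs(cm)) <= r_max) break
    # among all super-threshold pairs, drop the worst-ranked member
    involved <- unique(as.vector(which(abs(cm) > r_max, arr.ind = TRUE)))
    worst <- keep[involved][which.max(ranking[keep[involved]])]
    keep <- setdiff(keep, worst)
  }
  feature_set_spec(target, keep)
}

#' Feature set specification
#'
#' @param target `"arousal"`, `"valence"`, `"combined"` or a custom label.
#' @param members Feature names drawn from [feature_schema()].
#' @return A `feature_set_spec` object.
#' @export
feature_set_spec <- function(target, members) {
  members <- as.character(members)
  bad <- setdiff(members, feature_schema())
  if (length(bad) > 0)
    stop("unknown feature name(s): ", paste(bad, collapse = ", "))
  structure(list(target = target, members = members),
            class = "feature_set_spec")
}

#' @export
print.feature_set_spec <- function(x, ...) {
  cat(sprintf("<feature_set_spec> %s (%d features): %s\n", x$target,
              length(x$members), paste(x$members, collapse = ", ")))
  invisible(x)
}

#' Packaged predictor sets for the three classification targets
#'
#' The selected predictor sets used by the classifier presets: 6 features
#' for arousal-level estimation, 8 for valence levels and 7 for the joint
#' quadrant task, obtained by screening plus correlation pruning on the
#' study recordings and shipped as versioned fixtures so downstream stages
#' run without the original data.
#'
#' @param target `"arousal"`, `"valence"`, `"combined"`, or `"full"` for
#'   all 28 features.
#' @return A [feature_set_spec()].
#' @export
feature_set <- function(target = c("arousal", "valence", "combined",
                                   "full")) {
  target <- match.arg(target)
  members <- switch(target,
    arousal = c("fix_freq", "blink_freq", "pupil_mean", "fix_dur_kurt",
                "sac_dur_cv", "pupil_cv"),
    valence = c("fix_freq", "blink_freq", "sac_amp_median",
                "sac_dur_median", "pupil_mean", "fix_dur_kurt",
                "sac_dur_cv", "pupil_kurt"),
    combined = c("sac_freq", "blink_freq", "sac_amp_median", "pupil_mean",
                 "fix_dur_kurt", "sac_dur_cv", "pupil_kurt"),
    full = feature_schema())
  feature_set_spec(target, members)
}

#' Pupil-luminance confound check
#'
#' Pearson correlation between the pupil-diameter series and the per-frame
#' V (brightness) component of the stimulus video, with the conventional
#' strength categories: |r| < 0.20 very weak, < 0.40 weak, < 0.60
#' moderate, otherwise strong. The pupil series is block-averaged onto the
#' frame grid before correlating. A weak correlation justifies using the
#' raw tracker pupil diameter without luminance correction.
#'
#' @param pupil_t,pupil_mm Pupil sample times (s) and diameters (mm).
#' @param v_t,v Frame times (s) and V-component values (one per video
#'   frame).
#' @return A `luminance_check` list: `r`, `category`, `n` frames used.
#' @export
luminance_check <- function(pupil_t, pupil_mm, v_t, v) {
  stopifnot(length(pupil_t) == length(pupil_mm), length(v_t) == length(v))
  if (length(v_t) < 3) stop("need at least 3 video frames")
  # block-average pupil samples onto the frame intervals
  brk <- c(v_t, v_t[length(v_t)] + diff(v_t)[length(v_t) - 1])
  bin <- findInterval(pupil_t, brk, rightmost.closed = TRUE)
  ok <- bin >= 1 & bin <= length(v) & is.finite(pupil_mm)
  pm <- tapply(pupil_mm[ok], factor(bin[ok], levels = seq_along(v)), mean)
  keep <- is.finite(pm) & is.finite(v)
  if (sum(keep) < 3 || stats::sd(pm[keep]) == 0 || stats::sd(v[keep]) == 0)
    return(structure(list(r = NA_real_, category = NA_character_,
                          n = sum(keep)), class = "luminance_check"))
  r <- stats::cor(pm[keep], v[keep])
  structure(list(r = r, category = correlation_category(r), n = sum(keep)),
            class = "luminance_check")
}

#' Correlation strength category
#'
#' @param r Pearson correlation.
#' @return `"very weak"` (|r| < 0.20), `"weak"` (< 0.40), `"moderate"`
#'   (< 0.60) or `"strong"`.
#' @export
correlation_category <- function(r) {
  a <- abs(r)
  ifelse(a < 0.20, "very weak",
         ifelse(a < 0.40, "weak",
                ifelse(a < 0.60, "moderate", "strong")))
}
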