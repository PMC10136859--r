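.quadrant_map <- c(anger = "HANV", disgust = "HANV", sadness = "LANV",
                   tenderness = "LAPV", neutral = "MAMV")
.arousal_map <- c(anger = "HA", disgust = "HA", sadness = "LA",
                  tenderness = "LA", neutral = "MA")
.valence_map <- c(anger = "NV", disgust = "NV", sadness = "NV",
                  tenderness = "PV", neutral = "MV")

#' Affect label for an emotion
#'
#' Maps one of the five emotion labels to its fixed position in the
#' arousal-valence circumplex: anger and disgust are high arousal/negative
#' valence (HANV), sadness low arousal/negative valence (LANV), tenderness
#' low arousal/positive valence (LAPV), and neutral medium arousal/medium
#' valence (MAMV).
#'
#' @param emotion One of `"anger"`, `"disgust"`, `"sadness"`,
#'   `"tenderness"`, `"neutral"` (vectorized).
#' @return A data.frame with columns `emotion`, `arousal` (LA/MA/HA),
#'   `valence` (NV/MV/PV), `quadrant` (HANV/LANV/LAPV/MAMV).
#' @export
affect_label <- function(emotion) {
  emotion <- as.character(emotion)
  bad <- setdiff(unique(emotion), .emotions)
  if (length(bad) > 0)
    stop("unknown emotion(s): ", paste(bad, collapse = ", "))
  data.frame(emotion = emotion,
             arousal = unname(.arousal_map[emotion]),
             valence = unname(.valence_map[emotion]),
             quadrant = unname(.quadrant_map[emotion]),
             stringsAsFactors = FALSE)
}

#' Subjective emotion annotation from DES ratings
#'
#' Applies the self-assessment rule: an emotion is the subjective
#' annotation iff its rating is at least 4 (on the 0-10 differential
#' emotions scale) and at least 1 point higher than each of the other three
#' ratings; otherwise the recording is annotated neutral. Ties at the top
#' therefore fall back to neutral. Ratings are accepted as reals in
#' \[0, 10\] so that group-mean rating vectors can flow through the same
#' rule.
#'
#' @param ratings A data.frame (or named numeric vector for one rating)
#'   with columns `anger`, `disgust`, `sadness`, `tenderness`.
#' @param accept_min Minimum rating for an emotion to count (default 4).
#' @param margin Required lead over the runner-up (default 1, inclusive).
#' @return An affect-label data.frame as from [affect_label()], one row per
#'   rating row.
#' @export
subjective_annotation <- function(ratings, accept_min = 4, margin = 1) {
  if (is.numeric(ratings) && !is.data.frame(ratings))
    ratings <- as.data.frame(as.list(ratings))
  des <- c("anger", "disgust", "sadness", "tenderness")
  if (!all(des %in% names(ratings)))
    stop("ratings must have columns ", paste(des, collapse = ", "))
  m <- as.matrix(ratings[, des])
  if (any(!is.finite(m)) || any(m < 0) || any(m > 10))
    stop("ratings must lie in [0, 10]")
  lab <- apply(m, 1, function(r) {
    top <- which.max(r)
    if (r[top] >= accept_min && all(r[top] >= r[-top] + margin))
      des[top]
    else "neutral"
  })
  affect_label(lab)
}

#' Per-emotion hit rate
#'
#' Fraction of videos targeting each emotion for which the subjective
#' annotation equals the target.
#'
#' @param objective,subjective Character vectors of equal length with the
#'   target (objective) and self-reported (subjective) emotion per
#'   recording.
#' @return Named numeric vector over the target emotions present; a target
#'   with zero videos would be absent, targets are reported as fractions
#'   in \[0, 1\].
#' @export
hit_rate <- function(objective, subjective) {
  if (length(objective) == 0) stop("empty annotation list")
  stopifnot(length(objective) == length(subjective))
  tapply(subjective == objective, objective, mean)
}

#' Mean rating of each target emotion over its own videos
#'
#' @param ratings Data.frame with DES rating columns plus `participant_id`,
#'   `video_id`.
#' @param manifest Manifest data.frame (`participant_id`, `video_id`,
#'   `emotion`).
#' @return Named numeric vector: for each non-neutral target emotion, the
#'   mean of that emotion's own rating over its videos.
#' @export
mean_target_rating <- function(ratings, manifest) {
  mrg <- merge(ratings, manifest[, c("participant_id", "video_id", "emotion")],
               by = c("participant_id", "video_id"))
  if (nrow(mrg) == 0) stop("no ratings match the manifest")
  targets <- setdiff(unique(mrg$emotion), "neutral")
  out <- vapply(targets, function(e) mean(mrg[[e]][mrg$emotion == e]),
                numeric(1))
  sort(out, decreasing = TRUE)
}

#' Discreteness of the subjective annotations
#'
#' For recordings grouped by their subjective annotation, paired t-tests of
#' the annotated emotion's rating against each of the other three emotions'
#' ratings over the same recordings. A discretely felt emotion should score
#' significantly higher than the co-rated alternatives.
#'
#' @param ratings Data.frame with the four DES rating columns.
#' @param annotation Character vector of subjective annotations per row
#'   (neutral rows are skipped).
#' @return Data.frame with `annotation`, `versus`, `n`, `t`, `df`, `p`.
#'   Zero-variance paired differences are reported at their limits
#'   (`t = Inf`/`-Inf`/`0`, `p = 0`/`1`) with a warning.
#' @export
discreteness_test <- function(ratings, annotation) {
  des <- c("anger", "disgust", "sadness", "tenderness")
  stopifnot(all(des %in% names(ratings)),
            length(annotation) == nrow(ratings))
  out <- NULL
  for (emo in intersect(unique(annotation), des)) {
    rows <- which(annotation == emo)
    if (length(rows) < 2) next
    for (other in setdiff(des, emo)) {
      res <- paired_t(ratings[[emo]][rows], ratings[[other]][rows])
      out <- rbind(out, data.frame(annotation = emo, versus = other,
                                   n = length(rows), t = res$t,
                                   df = res$df, p = res$p))
    }
  }
  out
}

# Paired t-test with explicit zero-variance limit handling.
paired_t <- function(x, y) {
  d <- x - y
  n <- length(d)
  if (stats::sd(d) == 0) {
    warning("zero-variance paired difference: reporting limit values")
    m <- mean(d)
    return(list(t = if (m == 0) 0 else sign(m) * Inf, df = n - 1,
                p = if (m == 0) 1 else 0))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Annotate a session's ratings
#'
#' Joins the manifest with per-recording DES ratings, derives the
#' subjective annotation and attaches objective/subjective affect labels.
#'
#' @param ratings Data.frame with `participant_id`, `video_id` and the four
#'   DES rating columns.
#' @param manifest Manifest data.frame.
#' @return Data.frame with identifiers, ratings, `objective_emotion`, the
#'   subjective `emotion`, `arousal`, `valence`, `quadrant`.
#' @export
annotate_session <- function(ratings, manifest) {
  mrg <- merge(ratings,
               manifest[, c("participant_id", "video_id", "emotion")],
               by = c("participant_id", "video_id"))
  names(mrg)[names(mrg) == "emotion"] <- "objective_emotion"
  cbind(mrg, subjective_annotation(mrg))
}
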