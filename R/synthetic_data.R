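#' Synthetic eye-tracking recording generator
#'
#' Emits a binocular-style 240 Hz sample stream with known ground truth,
#' built as an alternating renewal process of fixations, optional blinks
#' at event boundaries, and saccades:
#' \itemize{
#' \item Fixation durations are drawn from the profile's left-truncated
#'   lognormal; fixation gaze jitters around the centroid with miniature
#'   motion whose per-sample speed is bounded well below the 45 deg/s
#'   detection threshold (a construction guarantee).
#' \item Saccades move along a great circle to an on-screen target at the
#'   drawn amplitude with a discrete trapezoidal velocity profile whose
#'   peak follows the main-sequence relation; every within-saccade sample
#'   pair moves at >= 60 deg/s, so detected event boundaries and endpoint
#'   amplitudes are exact.
#' \item Blinks are inserted between a fixation and the following saccade
#'   with the profile's rate-preserving probability; their interior samples
#'   have low confidence and missing pupil, and the blink interval is also
#'   reported in the tracker-style blink table.
#' \item Pupil diameter is baseline + per-recording baseline jitter + slow
#'   AR(1) drift + white noise, all zero-mean around the profile's target.
#' }
#' The stream ends at the end of the first fixation whose close reaches
#' `duration_s`, so every emitted event is complete.
#'
#' @param profile A [class_profile()].
#' @param duration_s Nominal recording length (s).
#' @param fs_hz Sampling rate (Hz).
#' @param seed Optional integer seed (recordings are reproducible given
#'   the seed).
#' @param motion_noise If `FALSE`, fixation samples sit exactly on the
#'   centroid (noiseless mode for boundary-recovery checks).
#' @param geom A [screen_geometry()].
#' @param pupil_offset_mm Additive pupil baseline offset (used by
#'   [generate_session()] for participant effects).
#' @param v_series Optional per-frame stimulus brightness series (list with
#'   `t` and `v`) to couple into the pupil, for exercising the
#'   pupil-luminance confound check; `v_gain_mm` scales the (negative)
#'   pupil response per unit of standardized V.
#' @param v_gain_mm Pupil response gain (mm per SD of V; 0 disables).
#' @param participant_id,video_id Identifiers stored on the recording.
#' @return A list with `recording` (a [raw_recording()]) and
#'   `ground_truth` (list with the exact event table, counts and the
#'   profile label).
#' @export
generate_recording <- function(profile, duration_s = 60, fs_hz = 240,
                               seed = NULL, motion_noise = TRUE,
                               geom = screen_geometry(),
                               pupil_offset_mm = 0,
                               v_series = NULL, v_gain_mm = 0,
                               participant_id = "synthetic",
                               video_id = "synthetic") {
  stopifnot(inherits(profile, "class_profile"), duration_s > 0, fs_hz > 0)
  if (!is.null(seed)) set.seed(seed)
  dt <- 1 / fs_hz
  n_max <- ceiling((duration_s + 20) * fs_hz) + 2
  P <- matrix(NA_real_, n_max, 3)
  closed <- logical(n_max)

  ncap <- ceiling(duration_s / (profile$mu_fix_s + profile$mu_sac_s)) + 50
  draw_cycles <- function(k) list(
    F = rtrunc_lnorm(k, profile$fix_meanlog, profile$fix_sdlog,
                     profile$min_fix_s),
    A = rtrunc_lnorm(k, profile$amp_meanlog, profile$amp_sdlog, 2),
    Bf = stats::runif(k) < profile$p_blink,
    Bd = stats::rlnorm(k, profile$blink_meanlog, profile$blink_sdlog))
  cyc <- draw_cycles(ncap)

  ev_type <- character(0)
  ev_start <- ev_end <- integer(0)
  ev_amp <- numeric(0)

  # start fixation centroid in the central part of the screen
  x0 <- stats::runif(1, -0.25, 0.25) * geom$width_mm
  y0 <- stats::runif(1, -0.25, 0.25) * geom$height_mm
  u <- normalize3(c(x0, y0, geom$distance_mm))
  P[1, ] <- u
  cur <- 1L
  i <- 0L
  repeat {
    i <- i + 1L
    if (i > length(cyc$F)) {
      more <- draw_cycles(ncap)
      cyc <- Map(c, cyc, more)
    }
    # ---- fixation ----
    mf <- max(14L, as.integer(round(cyc$F[i] * fs_hz)))
    basis <- tangent_basis(u)
    if (motion_noise) {
      eps <- matrix(pmin(pmax(stats::rnorm(2 * mf, 0, 0.02), -0.05), 0.05),
                    mf, 2)
      d <- apply(eps, 2, function(e)
        as.numeric(stats::filter(e, 0.6, method = "recursive")))
      d <- matrix(d, mf, 2) * pi / 180
      V <- cbind(u[1] + d[, 1] * basis$e1[1] + d[, 2] * basis$e2[1],
                 u[2] + d[, 1] * basis$e1[2] + d[, 2] * basis$e2[2],
                 u[3] + d[, 1] * basis$e1[3] + d[, 2] * basis$e2[3])
      V <- V / sqrt(rowSums(V^2))
    } else {
      V <- matrix(u, mf, 3, byrow = TRUE)
    }
    P[(cur + 1L):(cur + mf), ] <- V
    ev_type <- c(ev_type, "fixation")
    ev_start <- c(ev_start, cur); ev_end <- c(ev_end, cur + mf)
    ev_amp <- c(ev_amp, NA_real_)
    cur <- cur + mf
    if ((cur - 1L) / fs_hz >= duration_s) break
    u_cur <- P[cur, ]
    # ---- optional blink between fixation and next saccade ----
    if (cyc$Bf[i]) {
      mb <- max(4L, as.integer(round(cyc$Bd[i] * fs_hz)))
      P[(cur + 1L):(cur + mb), ] <- matrix(u_cur, mb, 3, byrow = TRUE)
      closed[(cur + 1L):(cur + mb - 1L)] <- TRUE
      ev_type <- c(ev_type, "blink")
      ev_start <- c(ev_start, cur); ev_end <- c(ev_end, cur + mb)
      ev_amp <- c(ev_amp, NA_real_)
      cur <- cur + mb
      u_cur <- P[cur, ]
    }
    # ---- saccade ----
    tg <- pick_saccade_target(u_cur, cyc$A[i], geom)
    pv <- profile$main_seq_a * (1 - exp(-tg$amp / profile$main_seq_b))
    ms <- max(4L, as.integer(round(tg$amp / (0.75 * pv) * fs_hz)))
    w <- saccade_weights(tg$amp, ms, floor_deg = 60 * dt)
    ms <- length(w)
    S <- slerp_path(u_cur, tg$w, cumsum(w) / sum(w), tg$amp * pi / 180)
    P[(cur + 1L):(cur + ms), ] <- S
    ev_type <- c(ev_type, "saccade")
    ev_start <- c(ev_start, cur); ev_end <- c(ev_end, cur + ms)
    ev_amp <- c(ev_amp, tg$amp)
    cur <- cur + ms
    u <- tg$w
  }

  n <- cur
  t <- (seq_len(n) - 1L) * dt
  closed <- closed[seq_len(n)]
  P <- P[seq_len(n), , drop = FALSE]

  # ---- pupil: baseline + slow AR(1) drift + white noise ----
  sd_tot <- profile$pupil_cv * profile$pupil_mean_mm
  sd_drift <- 0.8 * sd_tot
  sd_white <- 0.6 * sd_tot
  rho <- exp(-dt / 5)
  innov <- stats::rnorm(n, 0, sd_drift * sqrt(1 - rho^2))
  drift <- as.numeric(stats::filter(innov, rho, method = "recursive",
                                    init = stats::rnorm(1, 0, sd_drift)))
  baseline <- profile$pupil_mean_mm + pupil_offset_mm +
    stats::rnorm(1, 0, profile$pupil_baseline_sd_mm)
  pupil <- baseline + drift + stats::rnorm(n, 0, sd_white)
  if (!is.null(v_series) && v_gain_mm != 0) {
    vz <- (v_series$v - mean(v_series$v)) / stats::sd(v_series$v)
    pupil <- pupil - v_gain_mm *
      stats::approx(v_series$t, vz, xout = t, rule = 2)$y
  }
  pupil[closed] <- NA_real_

  conf <- stats::runif(n, 0.85, 1)
  conf[closed] <- stats::runif(sum(closed), 0.05, 0.35)

  gaze_x <- (geom$distance_mm * P[, 1] / P[, 3]) / geom$width_mm + 0.5
  gaze_y <- (geom$distance_mm * P[, 2] / P[, 3]) / geom$height_mm + 0.5

  bl <- ev_type == "blink"
  blinks <- cbind(start_s = t[ev_start[bl]], end_s = t[ev_end[bl]])

  rec <- raw_recording(participant_id, video_id, t = t, gaze_x = gaze_x,
                       gaze_y = gaze_y, pupil_mm = pupil, confidence = conf,
                       blinks = blinks, fs_hz = fs_hz,
                       clip_duration_s = duration_s)
  events <- data.frame(type = ev_type, start_sample = ev_start,
                       end_sample = ev_end, start_s = t[ev_start],
                       end_s = t[ev_end],
                       duration_ms = (t[ev_end] - t[ev_start]) * 1000,
                       amplitude_deg = ev_amp)
  list(recording = rec,
       ground_truth = list(events = events, label = profile$label,
                           n_fix = sum(ev_type == "fixation"),
                           n_sac = sum(ev_type == "saccade"),
                           n_blink = sum(bl),
                           pupil_baseline_mm = baseline))
}

normalize3 <- function(v) v / sqrt(sum(v^2))

# Orthonormal basis of the tangent plane at unit vector u.
tangent_basis <- function(u) {
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- normalize3(a - sum(a * u) * u)
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

# Great-circle interpolation from u toward w (separation ang_rad) at
# fractions f in (0, 1]; returns a length(f) x 3 matrix.
slerp_path <- function(u, w, f, ang_rad) {
  if (ang_rad < 1e-9) return(matrix(w, length(f), 3, byrow = TRUE))
  s <- sin(ang_rad)
  a <- sin((1 - f) * ang_rad) / s
  b <- sin(f * ang_rad) / s
  cbind(a * u[1] + b * w[1], a * u[2] + b * w[2], a * u[3] + b * w[3])
}

# On-screen target at great-angle amp_deg from u; falls back to aiming at
# the screen center (possibly shortening the saccade) when no direction
# keeps the target on screen.
pick_saccade_target <- function(u, amp_deg, geom, margin_mm = 5,
                                tries = 24) {
  basis <- tangent_basis(u)
  arad <- amp_deg * pi / 180
  phi <- stats::runif(tries, 0, 2 * pi)
  tx <- cos(phi) %*% t(basis$e1) + sin(phi) %*% t(basis$e2)
  W <- cos(arad) * matrix(u, tries, 3, byrow = TRUE) + sin(arad) * tx
  sx <- geom$distance_mm * W[, 1] / W[, 3]
  sy <- geom$distance_mm * W[, 2] / W[, 3]
  ok <- W[, 3] > 0.2 & abs(sx) <= geom$width_mm / 2 - margin_mm &
    abs(sy) <= geom$height_mm / 2 - margin_mm
  if (any(ok)) {
    k <- which(ok)[1]
    return(list(w = W[k, ], amp = amp_deg))
  }
  z <- c(0, 0, 1)
  psi <- 2 * asin(min(sqrt(sum((u - z)^2)) / 2, 1))
  ang <- min(arad, psi + 8 * pi / 180)
  tau <- z - cos(psi) * u
  tau <- if (sqrt(sum(tau^2)) < 1e-9) basis$e1 else normalize3(tau)
  w <- cos(ang) * u + sin(ang) * tau
  list(w = normalize3(w), amp = ang * 180 / pi)
}

# Discrete per-interval displacements (deg) of a trapezoidal velocity
# profile with total amplitude A over m intervals, floored so every
# interval exceeds the I-VT threshold with margin.
saccade_weights <- function(A, m, floor_deg) {
  m_feas <- max(2L, as.integer(floor(A / floor_deg)))
  m <- min(m, m_feas)
  r <- max(1L, as.integer(ceiling(0.25 * m)))
  shape <- if (m >= 2L * r + 1L) {
    up <- (seq_len(r) - 0.5) / r
    c(up, rep(1, m - 2L * r), rev(up))
  } else rep(1, m)
  w <- A * shape / sum(shape)
  if (any(w < floor_deg)) {
    deficit <- sum(pmax(floor_deg - w, 0))
    over <- w > floor_deg
    pool <- sum(w[over] - floor_deg)
    w[!over] <- floor_deg
    w[over] <- floor_deg + (w[over] - floor_deg) * (1 - deficit / pool)
  }
  w
}

.session_layout <- function() {
  utils::read.csv(text = "video_id,emotion,duration_s
v01,anger,77
v02,anger,115
v03,disgust,92
v04,disgust,60
v05,sadness,58
v06,sadness,120
v07,tenderness,121
v08,tenderness,79
v09,neutral,40
v10,neutral,43", stringsAsFactors = FALSE)
}

#' Generate a synthetic multi-participant session
#'
#' Emulates the study layout: each participant watches ten emotion-evoking
#' clips (two per target emotion including two neutral ones), each clip's
#' recording generated from the quadrant profile of its emotion with
#' participant-level random offsets (additive pupil baseline, log-scale
#' fixation-duration, blink-rate and amplitude factors) so that repeated
#' recordings of one participant are dependent, as the mixed-model
#' screening assumes. DES ratings are drawn around the rating row of each
#' video's emotion (neutral clips around a uniformly low base) with
#' truncation to \[0, 10\].
#'
#' @param n_participants Number of participants (>= 1).
#' @param seed Optional seed for full reproducibility.
#' @param duration_s Recording length override (NULL uses the per-clip
#'   layout durations).
#' @param fs_hz Sampling rate.
#' @param rating_noise_sd SD of the rating noise (0 reproduces the rating
#'   profile rows exactly).
#' @param participant_sd Named vector of participant random-effect SDs:
#'   `pupil` (mm, additive), `log_fix`, `log_blink`, `log_amp`
#'   (log-scale factors).
#' @param motion_noise Passed to [generate_recording()].
#' @return List with `manifest`, `recordings` (list), `ratings`
#'   (data.frame) and `ground_truths` (list).
#' @export
generate_session <- function(n_participants, seed = NULL, duration_s = NULL,
                             fs_hz = 240, rating_noise_sd = 1.5,
                             participant_sd = c(pupil = 0.3, log_fix = 0.08,
                                                log_blink = 0.15,
                                                log_amp = 0.03),
                             motion_noise = TRUE) {
  stopifnot(n_participants >= 1)
  if (!is.null(seed)) set.seed(seed)
  layout <- .session_layout()
  des <- des_rating_profile()
  rownames(des) <- des$annotation
  base_profiles <- lapply(stats::setNames(nm = c("HANV", "LANV", "LAPV",
                                                 "MAMV")), packaged_profile)
  recordings <- list()
  ground_truths <- list()
  manifest <- NULL
  ratings <- NULL
  for (p in seq_len(n_participants)) {
    pid <- sprintf("P%02d", p)
    off_pupil <- stats::rnorm(1, 0, participant_sd[["pupil"]])
    off_fix <- stats::rnorm(1, 0, participant_sd[["log_fix"]])
    off_blink <- stats::rnorm(1, 0, participant_sd[["log_blink"]])
    off_amp <- stats::rnorm(1, 0, participant_sd[["log_amp"]])
    for (vi in seq_len(nrow(layout))) {
      emo <- layout$emotion[vi]
      quad <- .quadrant_map[[emo]]
      bp <- base_profiles[[quad]]
      prof <- class_profile(
        bp$label,
        fix_dur_median_ms = bp$fix_dur_median_ms * exp(off_fix),
        fix_dur_cv = bp$fix_dur_cv,
        sac_amp_median_deg = bp$sac_amp_median_deg * exp(off_amp),
        sac_amp_cv = bp$sac_amp_cv,
        sac_pvel_mean_deg_s = bp$sac_pvel_mean_deg_s,
        blink_rate_hz = bp$blink_rate_hz * exp(off_blink),
        blink_dur_mean_ms = bp$blink_dur_mean_ms,
        blink_dur_cv = bp$blink_dur_cv,
        pupil_mean_mm = bp$pupil_mean_mm,
        pupil_cv = bp$pupil_cv,
        pupil_baseline_sd_mm = bp$pupil_baseline_sd_mm,
        emotions = bp$emotions)
      dur <- duration_s %||% layout$duration_s[vi]
      g <- generate_recording(prof, duration_s = dur, fs_hz = fs_hz,
                              motion_noise = motion_noise,
                              pupil_offset_mm = off_pupil,
                              participant_id = pid,
                              video_id = layout$video_id[vi])
      key <- paste(pid, layout$video_id[vi], sep = "_")
      recordings[[key]] <- g$recording
      ground_truths[[key]] <- g$ground_truth
      manifest <- rbind(manifest, data.frame(
        participant_id = pid, video_id = layout$video_id[vi],
        emotion = emo, duration_s = dur, stringsAsFactors = FALSE))
      base <- if (emo == "neutral") rep(0.5, 4)
              else unlist(des[emo, c("anger", "disgust", "sadness",
                                     "tenderness")])
      r <- pmin(pmax(base + stats::rnorm(4, 0, rating_noise_sd), 0), 10)
      ratings <- rbind(ratings, data.frame(
        participant_id = pid, video_id = layout$video_id[vi],
        anger = r[[1]], disgust = r[[2]], sadness = r[[3]],
        tenderness = r[[4]], stringsAsFactors = FALSE))
    }
  }
  list(manifest = validate_manifest(manifest), recordings = recordings,
       ratings = ratings, ground_truths = ground_truths)
}
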