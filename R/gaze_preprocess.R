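#' Convert normalized gaze to degrees of visual angle
#'
#' Projects normalized screen coordinates onto the physical display and
#' expresses gaze direction as per-axis angles relative to the screen-center
#' normal: `theta = atan(offset_from_center / viewing_distance)` in degrees.
#' Samples inside blink intervals or with detection confidence below
#' `confidence_threshold` are masked as invalid; off-screen samples keep
#' their angles but are flagged in `on_screen`.
#'
#' @param rec A [raw_recording()].
#' @param geom A [screen_geometry()].
#' @param confidence_threshold Samples below this confidence are invalid.
#' @return An `angular_gaze` object: `t`, `theta_x`, `theta_y` (deg),
#'   `valid` mask, `on_screen` mask, `fs_hz`, and (after
#'   [angular_velocity()]) `speed` in deg/s.
#' @export
to_visual_angle <- function(rec, geom = screen_geometry(),
                            confidence_threshold = 0.5) {
  stopifnot(inherits(rec, "raw_recording"), inherits(geom, "screen_geometry"))
  dx <- (rec$gaze_x - 0.5) * geom$width_mm
  dy <- (rec$gaze_y - 0.5) * geom$height_mm
  theta_x <- atan(dx / geom$distance_mm) * 180 / pi
  theta_y <- atan(dy / geom$distance_mm) * 180 / pi
  # strict interior: the interval's boundary samples are the last/first
  # well-tracked samples and stay usable
  in_blink <- in_intervals(rec$t, rec$blinks, strict = TRUE)
  valid <- is.finite(theta_x) & is.finite(theta_y) &
    rec$confidence >= confidence_threshold & !in_blink
  on_screen <- is.finite(rec$gaze_x) & is.finite(rec$gaze_y) &
    rec$gaze_x >= 0 & rec$gaze_x <= 1 & rec$gaze_y >= 0 & rec$gaze_y <= 1
  structure(list(t = rec$t, theta_x = theta_x, theta_y = theta_y,
                 valid = valid, on_screen = on_screen, fs_hz = rec$fs_hz,
                 speed = NULL, speed_valid = NULL),
            class = "angular_gaze")
}

# Unit gaze direction vectors (eye at origin, +z toward screen) from the
# per-axis angles. Exact inverse of the atan projection used above.
gaze_direction_vectors <- function(theta_x, theta_y) {
  tx <- tan(theta_x * pi / 180)
  ty <- tan(theta_y * pi / 180)
  nrm <- sqrt(tx^2 + ty^2 + 1)
  cbind(tx / nrm, ty / nrm, 1 / nrm)
}

# Great-circle angle (deg) between paired rows of two unit-vector matrices;
# 2*asin(|u-v|/2) is numerically stable for small separations.
great_angle_deg <- function(u, v) {
  d <- sqrt(rowSums((u - v)^2))
  2 * asin(pmin(d / 2, 1)) * 180 / pi
}

#' Sample-to-sample angular gaze velocity
#'
#' Computes the instantaneous angular speed between consecutive gaze
#' samples: the exact great-circle angle between the two 3-D gaze
#' directions divided by the time step. `speed[i]` spans samples `i` and
#' `i+1` (length `n - 1`); pairs touching an invalid sample are masked.
#'
#' @param series An `angular_gaze` object from [to_visual_angle()].
#' @return The series with `speed` (deg/s) and `speed_valid` filled in.
#' @export
angular_velocity <- function(series) {
  stopifnot(inherits(series, "angular_gaze"))
  n <- length(series$t)
  if (sum(series$valid) < 2) stop("need at least 2 valid samples")
  dt <- diff(series$t)
  if (any(dt <= 0)) stop("nonpositive time step in series")
  u <- gaze_direction_vectors(series$theta_x, series$theta_y)
  ang <- great_angle_deg(u[-n, , drop = FALSE], u[-1, , drop = FALSE])
  series$speed <- ang / dt
  series$speed_valid <- series$valid[-n] & series$valid[-1] &
    is.finite(series$speed)
  series$speed[!series$speed_valid] <- NA_real_
  series
}

#' Five-tap velocity denoising filter
#'
#' Replaces the angular speed series with a locally filtered version of
#' itself using a 5-sample window. The default method is a running median,
#' which removes isolated one-sample velocity spikes (the dominant
#' eye-tracker velocity artifact) while passing monotone ramps and plateaus
#' -- and therefore saccade on/offsets -- unchanged. A symmetric FIR
#' smoother is available via `method = "mean"` with a configurable
#' `kernel` (default uniform 1/5). Windows are truncated at the series
#' edges and at masked samples; output length equals input length and the
#' filtered maximum never exceeds the raw maximum.
#'
#' @param series An `angular_gaze` object with `speed` computed.
#' @param method `"median"` (default) or `"mean"`.
#' @param kernel Numeric weights for `method = "mean"`; normalized to sum 1.
#' @return The series with `speed` replaced by its filtered version.
#' @export
five_tap_velocity_filter <- function(series, method = c("median", "mean"),
                                     kernel = rep(1, 5) / 5) {
  stopifnot(inherits(series, "angular_gaze"))
  if (is.null(series$speed)) stop("speed not computed; run angular_velocity()")
  method <- match.arg(method)
  series$speed <- windowed_filter(series$speed, width = length(kernel),
                                  method = method, kernel = kernel)
  series$speed[!series$speed_valid] <- NA_real_
  series
}

# Truncated-window filter over a vector with NAs treated as missing.
# Windows truncate at series edges and at NA runs, so masked stretches
# (blinks) never leak into neighbouring values.
windowed_filter <- function(x, width = 5, method = "median",
                            kernel = rep(1, width) / width) {
  n <- length(x)
  if (n == 0) return(x)
  half <- (width - 1) %/% 2
  if (method == "median") {
    out <- x
    r <- rle(!is.na(x))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (j in which(r$values)) {
      idx <- starts[j]:ends[j]
      if (length(idx) >= width)
        out[idx] <- stats::runmed(x[idx], width, endrule = "median")
      else if (length(idx) >= 3)
        out[idx] <- stats::runmed(x[idx], 3, endrule = "median")
    }
    return(out)
  }
  ok <- !is.na(x)
  xa <- ifelse(ok, x, 0)
  num <- numeric(n)
  den <- numeric(n)
  for (j in -half:half) {
    k <- kernel[j + half + 1]
    src <- seq_len(n) + j
    inr <- src >= 1 & src <= n
    num[inr] <- num[inr] + k * xa[src[inr]]
    den[inr] <- den[inr] + k * ok[src[inr]]
  }
  out <- num / den
  out[!ok] <- NA_real_
  out
}

#' Preprocess a recording into a denoised angular gaze series
#'
#' Convenience chain: [to_visual_angle()], [angular_velocity()],
#' [five_tap_velocity_filter()].
#'
#' @inheritParams to_visual_angle
#' @param filter_method Passed to [five_tap_velocity_filter()]; `"none"`
#'   skips the filter.
#' @return An `angular_gaze` series with denoised `speed`.
#' @export
preprocess_gaze <- function(rec, geom = screen_geometry(),
                            confidence_threshold = 0.5,
                            filter_method = c("median", "mean", "none")) {
  filter_method <- match.arg(filter_method)
  s <- angular_velocity(to_visual_angle(rec, geom, confidence_threshold))
  if (filter_method != "none")
    s <- five_tap_velocity_filter(s, method = filter_method)
  s
}
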