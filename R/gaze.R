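# Eye, head and gaze pitch processing: IMU orientation fusion, the gaze
# image-coordinate map, zero-phase Butterworth smoothing, empirical baselines
# and per-step discretization. Sign convention throughout: positive pitch =
# looking up, negative = looking down.

.quat_mult <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

#' Pitch from a single accelerometer sample (static closed form)
#'
#' For a stationary sensor the accelerometer measures the gravity direction,
#' giving pitch `atan2(-ax, sqrt(ay^2 + az^2))` in the axis convention used by
#' the synthetic generator (x forward, z up at rest).
#'
#' @param accel length-3 accelerometer sample or n-by-3 matrix.
#' @return pitch in degrees.
#' @export
accel_pitch <- function(accel) {
  a <- rbind(accel)
  unname(atan2(-a[, 1], sqrt(a[, 2]^2 + a[, 3]^2)) * 180 / pi)
}

#' Head pitch from IMU data via Madgwick's orientation filter
#'
#' Gradient-descent IMU fusion: the orientation quaternion is propagated by
#' gyroscope integration and corrected toward the accelerometer gravity
#' direction with step size `beta`. Samples with zero accelerometer norm get a
#' gyro-only update. Pitch is extracted from the quaternion in degrees,
#' aligned to the input timestamps.
#'
#' @param t timestamps in seconds, strictly increasing.
#' @param accel n-by-3 accelerometer matrix (any consistent unit).
#' @param gyro n-by-3 gyroscope matrix, rad/s.
#' @param beta filter gain (0 = pure gyro integration).
#' @param q_init optional initial quaternion (w, x, y, z); by default
#'   initialised from the first non-zero accelerometer sample.
#' @return numeric vector of head pitch angles, degrees.
#' @export
madgwick_pitch <- function(t, accel, gyro, beta = 0.1, q_init = NULL) {
  accel <- rbind(accel); gyro <- rbind(gyro)
  n <- nrow(accel)
  if (length(t) != n || nrow(gyro) != n)
    stop("t, accel and gyro must have matching lengths")
  if (n > 1 && any(diff(t) <= 0)) stop("timestamps must be strictly increasing")
  q <- q_init
  if (is.null(q)) {
    nrm <- sqrt(rowSums(accel^2))
    k <- match(TRUE, nrm > 0)
    if (is.na(k)) q <- c(1, 0, 0, 0) else {
      a <- accel[k, ] / nrm[k]
      pitch <- atan2(-a[1], sqrt(a[2]^2 + a[3]^2))
      roll <- atan2(a[2], a[3])
      q <- .quat_mult(c(cos(pitch / 2), 0, sin(pitch / 2), 0),
                      c(cos(roll / 2), sin(roll / 2), 0, 0))
    }
  }
  q <- q / sqrt(sum(q^2))
  pitch_of <- function(q) asin(pmin(pmax(2 * (q[1] * q[3] - q[4] * q[2]),
                                         -1), 1)) * 180 / pi
  out <- numeric(n)
  out[1] <- pitch_of(q)
  for (i in seq_len(n)[-1]) {
    dt <- t[i] - t[i - 1]
    w <- gyro[i, ]
    qdot <- 0.5 * .quat_mult(q, c(0, w))
    a <- accel[i, ]
    nrm <- sqrt(sum(a^2))
    if (nrm > 0) {
      a <- a / nrm
      q1 <- q[1]; q2 <- q[2]; q3 <- q[3]; q4 <- q[4]
      f <- c(2 * (q2 * q4 - q1 * q3) - a[1],
             2 * (q1 * q2 + q3 * q4) - a[2],
             2 * (0.5 - q2^2 - q3^2) - a[3])
      grad <- c(-2 * q3 * f[1] + 2 * q2 * f[2],
                2 * q4 * f[1] + 2 * q1 * f[2] - 4 * q2 * f[3],
                -2 * q1 * f[1] + 2 * q4 * f[2] - 4 * q3 * f[3],
                2 * q2 * f[1] + 2 * q3 * f[2])
      gn <- sqrt(sum(grad^2))
      if (gn > 0) qdot <- qdot - beta * grad / gn
    }
    q <- q + qdot * dt
    q <- q / sqrt(sum(q^2))
    out[i] <- pitch_of(q)
  }
  out
}

#' Eye pitch from normalized gaze image coordinates
#'
#' Linear map from the normalized vertical gaze position in the scene-camera
#' image to an eye-in-head pitch angle: image centre maps to 0 degrees, the
#' top edge to `+vfov/2`, the bottom edge to `-vfov/2`. Coordinates outside
#' [0, 1] (blinks, tracking loss) are clamped with a warning.
#'
#' @param gaze_y normalized vertical image coordinate(s), 0 = top.
#' @param vfov vertical field of view in degrees (> 0).
#' @return eye pitch in degrees (positive = up).
#' @export
eye_pitch_from_gaze <- function(gaze_y, vfov = 82) {
  if (vfov <= 0) stop("vfov must be > 0")
  out_of_range <- !is.na(gaze_y) & (gaze_y < 0 | gaze_y > 1)
  if (any(out_of_range))
    warning(sprintf("%d gaze_y value(s) outside [0, 1] clamped",
                    sum(out_of_range)))
  (0.5 - pmin(pmax(gaze_y, 0), 1)) * vfov
}

#' Zero-phase Butterworth low-pass filter
#'
#' Fourth-order (by default) Butterworth low-pass applied forward and backward
#' (zero phase), so anticipation onsets are not shifted in time. The effective
#' magnitude response is the squared single-pass response; see
#' [butter_gain()].
#'
#' @param x numeric signal.
#' @param cutoff_hz cutoff frequency, Hz (< Nyquist).
#' @param fs sampling rate, Hz.
#' @param order filter order of the single pass.
#' @return filtered signal, same length as `x`.
#' @export
lowpass <- function(x, cutoff_hz, fs = 60, order = 4) {
  if (cutoff_hz >= fs / 2) stop("cutoff must be below the Nyquist frequency")
  if (cutoff_hz <= 0) stop("cutoff must be > 0")
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  as.numeric(signal::filtfilt(bf, x))
}

#' Analytic magnitude response of the digital Butterworth low-pass
#'
#' Closed-form gain of the bilinear-transform Butterworth design at frequency
#' `f`: `1 / sqrt(1 + (tan(pi f / fs) / tan(pi fc / fs))^(2 order))`, squared
#' when the filter is applied forward-backward.
#'
#' @param f frequency of interest, Hz.
#' @param cutoff_hz filter cutoff, Hz.
#' @param fs sampling rate, Hz.
#' @param order filter order.
#' @param zero_phase if TRUE, return the squared (two-pass) gain.
#' @return linear amplitude gain in [0, 1].
#' @export
butter_gain <- function(f, cutoff_hz, fs = 60, order = 4, zero_phase = TRUE) {
  g <- 1 / sqrt(1 + (tan(pi * f / fs) / tan(pi * cutoff_hz / fs))^(2 * order))
  if (zero_phase) g^2 else g
}

#' Per-frame eye/head/gaze pitch series from a frame table
#'
#' Either takes the direct `eye_pitch`/`head_pitch` columns or derives them
#' from the raw signals (gaze image coordinates through
#' [eye_pitch_from_gaze()]; head IMU through [madgwick_pitch()], with a
#' burn-in period blanked to the first converged value). Both angles are then
#' smoothed with zero-phase Butterworth low-pass filters (defaults: 4 Hz for
#' head, 8 Hz for eye, order 4) and summed into the gaze pitch.
#'
#' @param frames frame table (see [generate_session()] for the schema).
#' @param fs sampling rate, Hz.
#' @param use_raw derive angles from IMU + gaze coordinates instead of the
#'   direct angle columns.
#' @param vfov vertical field of view for the gaze map, degrees.
#' @param head_cutoff,eye_cutoff,order Butterworth parameters.
#' @param beta Madgwick gain for the raw path.
#' @param burn_in seconds of Madgwick output discarded (replaced by the first
#'   post-burn-in value) before filtering.
#' @return data.frame with `timestamp`, `theta` (eye), `alpha` (head),
#'   `gamma = theta + alpha`, degrees.
#' @export
pitch_series <- function(frames, fs = 60, use_raw = FALSE, vfov = 82,
                         head_cutoff = 4, eye_cutoff = 8, order = 4,
                         beta = 0.1, burn_in = 2) {
  if (use_raw) {
    theta <- eye_pitch_from_gaze(frames$gaze_y, vfov)
    alpha <- madgwick_pitch(frames$timestamp,
                            as.matrix(frames[, c("accel_x", "accel_y",
                                                 "accel_z")]),
                            as.matrix(frames[, c("gyro_x", "gyro_y",
                                                 "gyro_z")]),
                            beta = beta)
    k <- max(1L, min(length(alpha), ceiling(burn_in * fs)))
    alpha[seq_len(k - 1L)] <- alpha[k]
  } else {
    if (!all(c("eye_pitch", "head_pitch") %in% names(frames)))
      stop("frames lack eye_pitch/head_pitch columns; use use_raw = TRUE")
    theta <- frames$eye_pitch
    alpha <- frames$head_pitch
  }
  theta <- lowpass(theta, eye_cutoff, fs, order)
  alpha <- lowpass(alpha, head_cutoff, fs, order)
  data.frame(timestamp = frames$timestamp, theta = theta, alpha = alpha,
             gamma = theta + alpha)
}

#' Empirical gaze baseline during level walking
#'
#' Mean eye and head pitch over the frames of the baseline segment's steps,
#' excluding the segment's first six and last six steps.
#'
#' @param pitch pitch series from [pitch_series()].
#' @param baseline_steps steps of the baseline segment, in order.
#' @return list with `theta0`, `alpha0`, `gamma0 = theta0 + alpha0`.
#' @export
gaze_baseline <- function(pitch, baseline_steps) {
  n <- nrow(baseline_steps)
  if (n <= 12)
    stop(sprintf("baseline segment has only %d steps; need more than 12", n))
  interior <- baseline_steps[7:(n - 6), ]
  sel <- pitch$timestamp >= min(interior$t_start) &
    pitch$timestamp < max(interior$t_end)
  if (!any(sel)) stop("no frames inside the baseline interior")
  theta0 <- mean(pitch$theta[sel])
  alpha0 <- mean(pitch$alpha[sel])
  list(theta0 = theta0, alpha0 = alpha0, gamma0 = theta0 + alpha0)
}

#' Per-sample gaze deviations from the baseline
#'
#' @param pitch pitch series.
#' @param baseline list from [gaze_baseline()].
#' @return data.frame with `timestamp`, `dtheta`, `dalpha`,
#'   `dgamma = dtheta + dalpha`.
#' @export
gaze_deviations <- function(pitch, baseline) {
  dtheta <- pitch$theta - baseline$theta0
  dalpha <- pitch$alpha - baseline$alpha0
  data.frame(timestamp = pitch$timestamp, dtheta = dtheta, dalpha = dalpha,
             dgamma = dtheta + dalpha)
}

#' Discretize per-sample deviations into per-step means
#'
#' Each step receives the mean of each deviation over frames with
#' `t_start <= timestamp < t_end`. Steps without any frame get NA features
#' (excluded downstream).
#'
#' @param dev per-sample deviation table from [gaze_deviations()].
#' @param steps step table with `t_start`, `t_end`.
#' @return `steps` with added `dtheta`, `dalpha`, `dgamma` columns.
#' @export
stepwise_means <- function(dev, steps) {
  edges <- c(steps$t_start, steps$t_end[nrow(steps)])
  if (any(diff(edges) <= 0)) stop("step boundaries must be increasing")
  bin <- findInterval(dev$timestamp, edges)
  keep <- bin >= 1 & bin <= nrow(steps) &
    dev$timestamp < steps$t_end[pmin(pmax(bin, 1), nrow(steps))]
  bin <- factor(bin[keep], levels = seq_len(nrow(steps)))
  mean_by <- function(x) as.numeric(tapply(x[keep], bin, mean))
  steps$dtheta <- mean_by(dev$dtheta)
  steps$dalpha <- mean_by(dev$dalpha)
  steps$dgamma <- steps$dtheta + steps$dalpha
  steps
}
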