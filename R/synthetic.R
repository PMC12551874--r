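# Synthetic multimodal walking sessions with planted anticipatory dynamics.
#
# The generator plants, per step, mean deviations of head/eye pitch and of
# Hof-normalized step length/period: per-mode steady-state holds plus linear
# ramps over the configured onset window before each transition, ending at the
# category amplitude one step before the boundary. Realised per-step values
# (mean + per-step Gaussian noise) are recorded as ground truth so that the
# downstream pipeline can be checked against them.

# per-mode joint-angle signatures (degrees) used to synthesise hip/knee/ankle
# traces; offsets are well separated so label refinement by 1-NN is feasible
.mode_angles <- data.frame(
  mode = c("walk", "stairs_up", "stairs_down", "ramp_up", "ramp_down"),
  hip = c(20, 45, 10, 28, 15),
  knee_peak = c(60, 85, 70, 65, 55),
  ankle = c(0, 12, -10, 5, -5),
  dz_per_step = c(0, 0.17, -0.17, NA, NA),  # stairs riser height, m
  slope = c(0, NA, NA, 0.06, -0.06))        # ramp grade, dz/dx

.ramp_profile <- function(onset, amplitude, hold_prev) {
  # planted mean at steps -onset..-1 before a boundary; linear from the
  # current hold towards the amplitude, reaching it at step -1
  if (onset == 0) return(numeric(0))
  k <- onset:1                       # steps -onset .. -1
  hold_prev + (amplitude - hold_prev) * (onset - k + 1) / onset
}

#' Generate a synthetic multimodal walking session
#'
#' Produces 60 Hz frame records (foot first-contact indicators, 3-D foot
#' positions, sagittal hip/knee/ankle angles of both legs, head-mounted IMU
#' accelerometer/gyroscope, normalized gaze image coordinates, walk-mode
#' labels, plus direct eye/head pitch columns) together with the ground-truth
#' step table, planted per-step features, and true transition locations.
#'
#' Contact events are placed on the frame grid (step periods rounded to whole
#' frames); the rounded values are recorded as ground truth. Pitch signals are
#' piecewise constant per step before the downstream low-pass smoothing, so
#' with zero noise the planted per-step means are exact up to filter edge
#' effects. Head IMU data are synthesised from the head pitch trace
#' (accelerometer = rotated gravity, gyroscope = pitch rate) and eye pitch is
#' inverted through the same linear gaze-coordinate map used by
#' [eye_pitch_from_gaze()], so both the raw-signal and direct-angle entry
#' points of the gaze pipeline are exercised.
#'
#' @param course a [course_spec()].
#' @param effects an [effect_spec()].
#' @param participant a [participant_params()].
#' @param seed integer seed; identical seeds yield identical sessions.
#' @param fs sampling rate in Hz.
#' @param vfov vertical field of view (degrees) of the scene camera used for
#'   the gaze-coordinate map.
#' @return a list of class `walk_session` with elements `frames`, `steps`
#'   (ground-truth step table with planted features), `transitions`
#'   (boundary step indices and categories), `participant`, `course`,
#'   `effects`, `fs`, `vfov`.
#' @export
generate_session <- function(course, effects = default_effects(),
                             participant = participant_params(),
                             seed = effects$seed, fs = 60, vfov = 82) {
  stopifnot(inherits(course, "course_spec"), inherits(effects, "effect_spec"),
            inherits(participant, "participant_params"))
  if (fs <= 16) stop("sampling rate must exceed twice the highest filter cutoff")
  set.seed(as.integer(seed))
  nz <- effects$noise
  L <- participant$leg_length
  g <- participant$g
  l0n <- participant$step_length / L
  p0n <- participant$step_period / sqrt(L / g)

  n_seg <- length(course$modes)
  seg_of <- rep(seq_len(n_seg), course$n_steps)
  mode_of <- course$modes[seg_of]
  n_steps <- length(seg_of)

  # transition categories at each internal boundary
  bounds <- cumsum(course$n_steps)[-n_seg]      # last step index of segment i
  cat_tab <- effects$categories
  cat_row <- function(from, to) {
    i <- which(cat_tab$from == from & cat_tab$to == to)
    if (length(i) == 0)
      stop(sprintf("no effect category for transition %s -> %s", from, to))
    cat_tab[i[1], ]
  }
  # gait holds: shift of the category entering each segment (0 for segment 1)
  hold_l <- numeric(n_seg); hold_p <- numeric(n_seg)
  for (i in seq_len(n_seg)[-1]) {
    cr <- cat_row(course$modes[i - 1], course$modes[i])
    hold_l[i] <- cr$step_length_shift
    hold_p[i] <- cr$step_period_shift
  }
  gh <- effects$gaze_holds
  hold_head <- gh$head[match(course$modes, gh$mode)]
  hold_eye <- gh$eye[match(course$modes, gh$mode)]

  # planted per-step mean deviations
  m_dl <- hold_l[seg_of]; m_dp <- hold_p[seg_of]
  m_da <- hold_head[seg_of]; m_dt <- hold_eye[seg_of]
  for (bi in seq_along(bounds)) {
    b <- bounds[bi]
    i <- seg_of[b]
    cr <- cat_row(course$modes[i], course$modes[i + 1])
    plant <- function(m, onset, amp, hold_prev) {
      onset <- as.integer(onset)
      if (onset > 0) {
        if (onset >= course$n_steps[i])
          stop(sprintf("segment %d (%s) too short for onset of %d steps",
                       i, course$modes[i], onset))
        idx <- (b - onset + 1):b
        m[idx] <- .ramp_profile(onset, amp, hold_prev)
      }
      m
    }
    m_da <- plant(m_da, cr$head_onset, cr$head_amplitude, hold_head[i])
    m_dt <- plant(m_dt, cr$eye_onset, cr$eye_amplitude, hold_eye[i])
    m_dl <- plant(m_dl, cr$gait_onset, cr$step_length_shift, hold_l[i])
    m_dp <- plant(m_dp, cr$gait_onset, cr$step_period_shift, hold_p[i])
  }

  # realised per-step values: planted mean + per-step noise
  dl <- m_dl + stats::rnorm(n_steps, 0, nz$step_length)
  dp <- m_dp + stats::rnorm(n_steps, 0, nz$step_period)
  da <- m_da + stats::rnorm(n_steps, 0, nz$head_deg)
  dt <- m_dt + stats::rnorm(n_steps, 0, nz$eye_deg)

  dt_frame <- 1 / fs
  l_phys <- pmax((l0n + dl) * L, 0.05)
  p_phys <- pmax(round((p0n + dp) * sqrt(L / g) * fs), 6) / fs
  dl <- l_phys / L - l0n                        # record post-clamp truth
  dp <- p_phys / sqrt(L / g) - p0n              # record post-rounding truth

  # contact events: n_steps + 1 events, feet alternating, grid-aligned
  ev_t <- cumsum(c(0.5, p_phys))
  ev_foot <- rep_len(c("left", "right"), n_steps + 1)
  t_end <- ev_t[n_steps + 1] + 0.5
  tt <- seq(0, by = dt_frame, length.out = floor(t_end / dt_frame) + 1L)
  n_fr <- length(tt)
  ev_frame <- as.integer(round(ev_t * fs)) + 1L

  # horizontal/vertical split of each step's displacement by terrain
  ma <- .mode_angles[match(mode_of, .mode_angles$mode), ]
  dz <- ifelse(!is.na(ma$dz_per_step), ma$dz_per_step, 0)
  dz <- ifelse(!is.na(ma$slope) & ma$slope != 0,
               ma$slope * l_phys / sqrt(1 + ma$slope^2), dz)
  dz <- ifelse(abs(dz) >= l_phys, 0, dz)
  dx <- sqrt(l_phys^2 - dz^2)
  ev_x <- cumsum(c(0, dx)); ev_z <- cumsum(c(0, dz))

  foot_series <- function(foot) {
    sel <- ev_foot == foot
    x <- stats::approx(ev_t[sel], ev_x[sel], xout = tt, rule = 2)$y
    z <- stats::approx(ev_t[sel], ev_z[sel], xout = tt, rule = 2)$y
    cbind(x = x, y = 0, z = z)
  }
  pos_l <- foot_series("left"); pos_r <- foot_series("right")

  # step index and within-step phase per frame
  j_fr <- pmin(pmax(findInterval(tt, ev_t), 1L), n_steps)
  u_fr <- pmin(pmax((tt - ev_t[j_fr]) / p_phys[j_fr], 0), 1)
  swing_fr <- ev_foot[j_fr + 1L]                # leg landing at step end
  mode_fr <- mode_of[j_fr]
  maf <- .mode_angles[match(mode_fr, .mode_angles$mode), ]
  bump <- exp(-((u_fr - effects$knee_phase) / 0.15)^2)
  knee_sw <- 8 + (maf$knee_peak - 8) * bump
  knee_st <- rep(8, n_fr)
  an <- function() stats::rnorm(n_fr, 0, nz$angle_frame_deg)
  knee_l <- ifelse(swing_fr == "left", knee_sw, knee_st) + an()
  knee_r <- ifelse(swing_fr == "right", knee_sw, knee_st) + an()
  hip_sw <- maf$hip + 10 * sinpi(u_fr)
  hip_st <- maf$hip - 5
  hip_l <- ifelse(swing_fr == "left", hip_sw, hip_st) + an()
  hip_r <- ifelse(swing_fr == "right", hip_sw, hip_st) + an()
  ankle_sw <- maf$ankle + 6 * sinpi(2 * u_fr)
  ankle_l <- ifelse(swing_fr == "left", ankle_sw, maf$ankle) + an()
  ankle_r <- ifelse(swing_fr == "right", ankle_sw, maf$ankle) + an()

  # pitch traces: piecewise constant per step + frame jitter
  head_pitch <- participant$head_pitch0 + da[j_fr] + an()
  eye_pitch <- participant$eye_pitch0 + dt[j_fr] + an()
  gaze_x <- 0.5 + stats::rnorm(n_fr, 0, nz$gaze_xy)
  gaze_y <- pmin(pmax(0.5 - eye_pitch / vfov +
                        stats::rnorm(n_fr, 0, nz$gaze_xy), 0), 1)

  # head IMU consistent with the head pitch trace
  a_rad <- head_pitch * pi / 180
  gy <- c(diff(a_rad), 0) * fs
  accel <- cbind(-sin(a_rad) * g + stats::rnorm(n_fr, 0, nz$accel),
                 stats::rnorm(n_fr, 0, nz$accel),
                 cos(a_rad) * g + stats::rnorm(n_fr, 0, nz$accel))
  gyro <- cbind(stats::rnorm(n_fr, 0, nz$gyro),
                gy + stats::rnorm(n_fr, 0, nz$gyro),
                stats::rnorm(n_fr, 0, nz$gyro))

  left_contact <- right_contact <- integer(n_fr)
  left_contact[ev_frame[ev_foot == "left"]] <- 1L
  right_contact[ev_frame[ev_foot == "right"]] <- 1L

  frames <- data.frame(
    timestamp = tt, left_contact = left_contact,
    right_contact = right_contact,
    foot_l_x = pos_l[, 1], foot_l_y = pos_l[, 2], foot_l_z = pos_l[, 3],
    foot_r_x = pos_r[, 1], foot_r_y = pos_r[, 2], foot_r_z = pos_r[, 3],
    knee_l = knee_l, knee_r = knee_r, hip_l = hip_l, hip_r = hip_r,
    ankle_l = ankle_l, ankle_r = ankle_r,
    accel_x = accel[, 1], accel_y = accel[, 2], accel_z = accel[, 3],
    gyro_x = gyro[, 1], gyro_y = gyro[, 2], gyro_z = gyro[, 3],
    gaze_x = gaze_x, gaze_y = gaze_y,
    eye_pitch = eye_pitch, head_pitch = head_pitch,
    mode_label = mode_fr)

  steps <- data.frame(
    index = seq_len(n_steps), foot = ev_foot[seq_len(n_steps)],
    t_start = ev_t[seq_len(n_steps)], t_end = ev_t[-1],
    mode_label = mode_of, segment = seg_of, valid = TRUE,
    l_norm = l_phys / L, p_norm = p_phys / sqrt(L / g),
    dl_norm = dl, dp_norm = dp, dalpha = da, dtheta = dt,
    m_dl = m_dl, m_dp = m_dp, m_dalpha = m_da, m_dtheta = m_dt)

  transitions <- data.frame(
    step_index = bounds,
    from = course$modes[seq_len(n_seg - 1)],
    to = course$modes[-1])

  structure(list(frames = frames, steps = steps, transitions = transitions,
                 participant = participant, course = course, effects = effects,
                 fs = fs, vfov = vfov, seed = as.integer(seed)),
            class = "walk_session")
}

#' Jitter walk-mode labels around transitions
#'
#' Emulates the imprecision of manually assigned walk-mode labels: each true
#' transition boundary is moved by a uniformly random integer offset in
#' `[-flip_window, flip_window]` steps, and frame labels are rewritten
#' accordingly. Ground truth (the step table and transition list) is retained
#' unchanged in the session.
#'
#' @param session a `walk_session`.
#' @param flip_window maximum boundary displacement in steps (>= 0).
#' @param seed integer seed for reproducible offsets.
#' @return the session with corrupted `frames$mode_label`; the applied offsets
#'   are stored in `session$label_offsets`.
#' @export
corrupt_labels <- function(session, flip_window = 2L, seed = 1L) {
  stopifnot(inherits(session, "walk_session"))
  flip_window <- as.integer(flip_window)
  if (flip_window < 0) stop("flip_window must be >= 0")
  set.seed(as.integer(seed))
  offsets <- if (flip_window == 0) rep(0L, nrow(session$transitions)) else
    sample(seq(-flip_window, flip_window), nrow(session$transitions),
           replace = TRUE)
  st <- session$steps
  lab <- st$mode_label
  for (i in seq_along(offsets)) {
    b <- session$transitions$step_index[i]
    d <- offsets[i]
    if (d > 0) {        # boundary moved later: extend the from-mode
      idx <- (b + 1):min(b + d, nrow(st))
      lab[idx] <- session$transitions$from[i]
    } else if (d < 0) { # boundary moved earlier: extend the to-mode
      idx <- max(b + 1 + d, 1):b
      lab[idx] <- session$transitions$to[i]
    }
  }
  j_fr <- pmin(pmax(findInterval(session$frames$timestamp, st$t_start), 1L),
               nrow(st))
  session$frames$mode_label <- lab[j_fr]
  session$label_offsets <- offsets
  session
}
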