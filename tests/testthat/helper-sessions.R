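# Shared fixtures: tiny hand-built frame tables and generated study regimes.

# minimal frame table from contact events; knee bumps for the swinging leg are
# placed at a configurable phase of each step
mini_frames <- function(events, knee_phase = 0.5, fs = 60, tail_s = 0.3,
                        mode = "walk") {
  stopifnot(is.data.frame(events), all(events$foot %in% c("left", "right")))
  t_max <- max(events$t) + tail_s
  tt <- seq(0, t_max, by = 1 / fs)
  n <- length(tt)
  fr <- data.frame(timestamp = tt, left_contact = 0L, right_contact = 0L,
                   foot_l_x = 0, foot_l_y = 0, foot_l_z = 0,
                   foot_r_x = 0, foot_r_y = 0, foot_r_z = 0,
                   knee_l = 5, knee_r = 5, hip_l = 20, hip_r = 20,
                   ankle_l = 0, ankle_r = 0,
                   accel_x = 0, accel_y = 0, accel_z = 9.81,
                   gyro_x = 0, gyro_y = 0, gyro_z = 0,
                   gaze_x = 0.5, gaze_y = 0.5,
                   eye_pitch = 0, head_pitch = 0,
                   mode_label = mode)
  kp <- rep_len(knee_phase, max(nrow(events) - 1, 1))
  for (i in seq_len(nrow(events))) {
    k <- round(events$t[i] * fs) + 1L
    col <- if (events$foot[i] == "left") "left_contact" else "right_contact"
    fr[[col]][k] <- 1L
    if (i > 1) {
      # swing bump of the leg landing at event i, peak at phase kp[i-1]
      t0 <- events$t[i - 1]; t1 <- events$t[i]
      u <- (tt - t0) / (t1 - t0)
      sel <- u >= 0 & u < 1
      kcol <- if (events$foot[i] == "left") "knee_l" else "knee_r"
      fr[[kcol]][sel] <- pmax(fr[[kcol]][sel],
                              5 + 55 * exp(-((u[sel] - kp[i - 1]) / 0.1)^2))
    }
  }
  fr
}

alternating_events <- function(n, period = 0.5, start = 0.5,
                               first = "left") {
  feet <- rep_len(c(first, setdiff(c("left", "right"), first)), n)
  data.frame(t = start + period * (seq_len(n) - 1), foot = feet)
}

# study regime: repeated walk -> stairs_up laps with the default planted
# anticipatory effects, processed through the full pipeline and IQR-filtered
stairs_regime_course <- function(n_transitions = 50) {
  modes <- c(rep(c("walk", "stairs_up"), n_transitions), "walk")
  course_spec(modes, rep(13L, length(modes)), baseline_segment = 1L)
}

make_stairs_regime <- function(seed, n_transitions = 50, flip_window = 2) {
  course <- stairs_regime_course(n_transitions)
  ses <- generate_session(course, default_effects(), participant_params(),
                          seed = seed)
  ses <- corrupt_labels(ses, flip_window = flip_window, seed = seed + 1L)
  feats <- process_session(ses$frames, ses$participant$leg_length,
                           pipeline_config())
  tr <- iqr_filter(extract_transitions(feats))
  tr[tr$category == "walk – stairs_up", ]
}

# step-table fixture with a single labeled transition; features are small
# random numbers so all cells are complete
transition_step_table <- function(n_before = 15, n_after = 15,
                                  from = "walk", to = "stairs_up", seed = 1) {
  set.seed(seed)
  n <- n_before + n_after
  data.frame(index = seq_len(n),
             foot = rep_len(c("left", "right"), n),
             t_start = 0.5 * (seq_len(n) - 1),
             t_end = 0.5 * seq_len(n),
             mode_label = rep(c(from, to), c(n_before, n_after)),
             valid = TRUE,
             dl_norm = rnorm(n, 0, 0.01), dp_norm = rnorm(n, 0, 0.01),
             dtheta = rnorm(n), dalpha = rnorm(n), dgamma = rnorm(n))
}

zero_noise_effects <- function(head_onset = 6, head_amplitude = -30) {
  cats <- data.frame(
    from = c("walk", "stairs_down"), to = c("stairs_down", "walk"),
    head_onset = c(head_onset, 0), eye_onset = c(4, 0), gait_onset = c(2, 0),
    head_amplitude = c(head_amplitude, 0), eye_amplitude = c(-20, 0),
    step_length_shift = c(-0.3, 0), step_period_shift = c(0.08, 0))
  nz <- list(head_deg = 0, eye_deg = 0, step_length = 0, step_period = 0,
             angle_frame_deg = 0, accel = 0, gyro = 0, gaze_xy = 0)
  effect_spec(cats, gaze_holds = NULL, noise = nz)
}
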