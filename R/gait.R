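# Step detection, validation, and Hof-normalized gait features.

.contact_edges <- function(x) which(x == 1 & c(0L, x[-length(x)]) != 1)

#' Detect and validate steps from per-foot first-contact indicators
#'
#' A step runs from one foot's first ground contact (rising edge of the
#' contact indicator) to the other foot's next first contact. A step is
#' flagged invalid when (a) the foot contacting at its end is the same as the
#' foot that started it (violating the alternating-feet plausibility rule),
#' (b) the swinging leg's sagittal knee-angle maximum falls outside the
#' central 10--90% of the step period, or (c) either contact coincides with a
#' simultaneous contact of both feet on the same frame. No step is silently
#' dropped: all detected steps are returned with validity flags.
#'
#' @param frames frame table with columns `timestamp`, `left_contact`,
#'   `right_contact`, `knee_l`, `knee_r` and `mode_label`.
#' @return data.frame with one row per step: `index`, `foot`, `t_start`,
#'   `t_end`, `mode_label`, `valid`.
#' @export
detect_steps <- function(frames) {
  tt <- frames$timestamp
  if (any(diff(tt) <= 0)) stop("timestamps must be strictly increasing")
  le <- .contact_edges(frames$left_contact)
  re <- .contact_edges(frames$right_contact)
  if (length(le) + length(re) == 0) {
    warning("no foot contacts found")
    return(data.frame(index = integer(), foot = character(),
                      t_start = numeric(), t_end = numeric(),
                      mode_label = character(), valid = logical()))
  }
  ev <- data.frame(frame = c(le, re),
                   foot = rep(c("left", "right"), c(length(le), length(re))))
  ev <- ev[order(ev$frame, ev$foot), ]
  ev$tie <- ev$frame %in% ev$frame[duplicated(ev$frame)]
  n_ev <- nrow(ev)
  if (n_ev < 2) {
    warning("fewer than two contacts; no steps")
    return(data.frame(index = integer(), foot = character(),
                      t_start = numeric(), t_end = numeric(),
                      mode_label = character(), valid = logical()))
  }
  i <- seq_len(n_ev - 1)
  t_start <- tt[ev$frame[i]]
  t_end <- tt[ev$frame[i + 1]]
  alt_ok <- ev$foot[i + 1] != ev$foot[i]
  tie_ok <- !ev$tie[i] & !ev$tie[i + 1]

  knee_ok <- logical(n_ev - 1)
  for (s in i) {
    sw <- ev$foot[s + 1]
    fr <- ev$frame[s]:(ev$frame[s + 1] - 1L)
    ang <- if (sw == "left") frames$knee_l[fr] else frames$knee_r[fr]
    if (length(ang) == 0 || all(is.na(ang))) { knee_ok[s] <- FALSE; next }
    k <- fr[which.max(ang)]                    # earliest frame on plateaus
    phase <- (tt[k] - t_start[s]) / (t_end[s] - t_start[s])
    knee_ok[s] <- phase >= 0.10 & phase <= 0.90
  }
  lab <- if ("mode_label" %in% names(frames))
    frames$mode_label[ev$frame[i]] else rep(NA_character_, n_ev - 1)
  data.frame(index = i, foot = ev$foot[i], t_start = t_start, t_end = t_end,
             mode_label = lab, valid = alt_ok & tie_ok & knee_ok)
}

#' Step length and period from foot positions at contact times
#'
#' Step length is the full 3-D Euclidean distance between the position of the
#' starting foot at the step's first ground contact and the position of the
#' opposite foot at its next first contact; the step period is the time
#' between the two contacts. Steps with a missing position at either contact
#' are marked invalid.
#'
#' @param steps step table from [detect_steps()].
#' @param frames frame table with `foot_l_*`/`foot_r_*` position columns.
#' @return `steps` with added columns `l` (m) and `p` (s), and `valid`
#'   downgraded where positions are missing.
#' @export
step_metrics <- function(steps, frames) {
  tt <- frames$timestamp
  pos_l <- as.matrix(frames[, c("foot_l_x", "foot_l_y", "foot_l_z")])
  pos_r <- as.matrix(frames[, c("foot_r_x", "foot_r_y", "foot_r_z")])
  frame_at <- function(t) {
    k <- findInterval(t - 1e-9, tt) + 1L  # first frame with timestamp >= t
    k[k > length(tt)] <- NA_integer_
    k
  }
  k1 <- frame_at(steps$t_start)
  k2 <- frame_at(steps$t_end)
  left_first <- steps$foot == "left"
  # starting foot position at t_start, opposite foot position at t_end
  p1 <- matrix(NA_real_, nrow(steps), 3)
  p2 <- matrix(NA_real_, nrow(steps), 3)
  ok1 <- !is.na(k1); ok2 <- !is.na(k2)
  p1[ok1 & left_first, ] <- pos_l[k1[ok1 & left_first], , drop = FALSE]
  p1[ok1 & !left_first, ] <- pos_r[k1[ok1 & !left_first], , drop = FALSE]
  p2[ok2 & left_first, ] <- pos_r[k2[ok2 & left_first], , drop = FALSE]
  p2[ok2 & !left_first, ] <- pos_l[k2[ok2 & !left_first], , drop = FALSE]
  steps$l <- sqrt(rowSums((p2 - p1)^2))
  steps$p <- steps$t_end - steps$t_start
  steps$valid <- steps$valid & !is.na(steps$l)
  steps
}

#' Hof dimensionless normalization of gait measures
#'
#' Scales step length by leg length and step period by the pendulum time
#' scale: `l_norm = l / L`, `p_norm = p / sqrt(L / g)`.
#'
#' @param l step length(s), m.
#' @param p step period(s), s.
#' @param L leg length, m (> 0).
#' @param g gravitational acceleration, m/s^2.
#' @return list with vectors `l_norm` and `p_norm`.
#' @export
hof_normalize <- function(l, p, L, g = 9.81) {
  if (length(L) != 1 || is.na(L) || L <= 0) stop("leg length L must be > 0")
  list(l_norm = l / L, p_norm = p / sqrt(L / g))
}

#' Level-walk gait baseline
#'
#' Mean normalized step length and period over the baseline segment's valid
#' steps, excluding the segment's first six and last six steps (considered
#' part of the adjacent walk-mode transitions).
#'
#' @param steps steps of the baseline segment, in order, with columns
#'   `l_norm`, `p_norm`, `valid`.
#' @return list with `l0` and `p0`.
#' @export
gait_baseline <- function(steps) {
  n <- nrow(steps)
  if (n <= 12)
    stop(sprintf("baseline segment has only %d steps; need more than 12", n))
  interior <- steps[7:(n - 6), ]
  interior <- interior[interior$valid & !is.na(interior$l_norm), ]
  if (nrow(interior) == 0) stop("no valid interior baseline steps")
  list(l0 = mean(interior$l_norm), p0 = mean(interior$p_norm))
}

#' Gait deviations from the empirical baseline
#'
#' @param steps step table with `l_norm`, `p_norm`.
#' @param baseline list with `l0`, `p0` from [gait_baseline()].
#' @return `steps` with added `dl_norm = l_norm - l0` and
#'   `dp_norm = p_norm - p0`.
#' @export
gait_deviations <- function(steps, baseline) {
  steps$dl_norm <- steps$l_norm - baseline$l0
  steps$dp_norm <- steps$p_norm - baseline$p0
  steps
}

#' Invalid-step percentage
#'
#' Share of invalid steps among all detected steps of a walk mode, in percent.
#'
#' @param valid,invalid step counts.
#' @param digits rounding of the printed percentage.
#' @return percentage of invalid steps.
#' @export
invalid_percentage <- function(valid, invalid, digits = 2) {
  if (any(valid < 0) || any(invalid < 0)) stop("counts must be non-negative")
  round(100 * invalid / (valid + invalid), digits)
}

#' Step accounting by walk mode
#'
#' Valid/invalid step counts and invalid percentages per walk mode plus a
#' total row, mirroring the usual quality-control accounting of step
#' detection.
#'
#' @param steps step table with `mode_label` and `valid`.
#' @return data.frame with columns `mode_label`, `valid_steps`,
#'   `invalid_steps`, `invalid_pct`.
#' @export
step_accounting <- function(steps) {
  agg <- stats::aggregate(cbind(valid_steps = steps$valid,
                                invalid_steps = !steps$valid),
                          by = list(mode_label = steps$mode_label), FUN = sum)
  agg <- rbind(agg, data.frame(mode_label = "total",
                               valid_steps = sum(steps$valid),
                               invalid_steps = sum(!steps$valid)))
  agg$invalid_pct <- invalid_percentage(agg$valid_steps, agg$invalid_steps)
  agg
}
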