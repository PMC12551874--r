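# Per-step feature assembly: gait and gaze deviations from level-walk
# baselines, one row per detected step.

#' Segment ids from per-step walk-mode labels
#'
#' Consecutive runs of equal mode labels form segments.
#'
#' @param mode_label character vector of per-step labels.
#' @return integer segment id per step.
#' @export
step_segments <- function(mode_label) {
  r <- rle(as.character(mode_label))
  rep(seq_along(r$lengths), r$lengths)
}

#' Compute per-step gait and gaze features
#'
#' Runs the feature chain on a detected (and label-refined) step table:
#' step length/period, Hof normalization, empirical level-walk baselines from
#' the designated baseline segment (excluding its first and last six steps),
#' gait deviations, filtered pitch series, gaze baseline and per-step gaze
#' deviation means.
#'
#' @param frames frame table.
#' @param steps step table from [detect_steps()] (mode labels final).
#' @param leg_length participant leg length, m.
#' @param baseline_segment index of the baseline segment among the step-label
#'   runs; default: the longest walk segment.
#' @param fs sampling rate, Hz.
#' @param use_raw,vfov,head_cutoff,eye_cutoff,order,beta,burn_in passed to
#'   [pitch_series()].
#' @return the step table with columns `segment`, `l`, `p`, `l_norm`,
#'   `p_norm`, `dl_norm`, `dp_norm`, `dtheta`, `dalpha`, `dgamma`; the
#'   baselines are attached as attribute `"baseline"`.
#' @export
compute_step_features <- function(frames, steps, leg_length,
                                  baseline_segment = NULL, fs = 60,
                                  use_raw = FALSE, vfov = 82, head_cutoff = 4,
                                  eye_cutoff = 8, order = 4, beta = 0.1,
                                  burn_in = 2) {
  if (nrow(steps) == 0) stop("empty step table")
  steps <- step_metrics(steps, frames)
  hn <- hof_normalize(steps$l, steps$p, leg_length)
  steps$l_norm <- hn$l_norm
  steps$p_norm <- hn$p_norm
  steps$segment <- step_segments(steps$mode_label)

  seg_modes <- tapply(steps$mode_label, steps$segment,
                      function(x) as.character(x[1]))
  if (is.null(baseline_segment)) {
    walks <- which(seg_modes == "walk")
    if (length(walks) == 0) stop("no walk segment available for the baseline")
    sizes <- table(steps$segment)[walks]
    baseline_segment <- walks[which.max(sizes)]
  }
  if (seg_modes[baseline_segment] != "walk")
    stop("baseline segment must be a walk segment")
  base_steps <- steps[steps$segment == baseline_segment, ]

  gb <- gait_baseline(base_steps)
  steps <- gait_deviations(steps, gb)

  pitch <- pitch_series(frames, fs = fs, use_raw = use_raw, vfov = vfov,
                        head_cutoff = head_cutoff, eye_cutoff = eye_cutoff,
                        order = order, beta = beta, burn_in = burn_in)
  zb <- gaze_baseline(pitch, base_steps)
  dev <- gaze_deviations(pitch, zb)
  steps <- stepwise_means(dev, steps)
  attr(steps, "baseline") <- c(gb, zb,
                               list(baseline_segment = baseline_segment))
  steps
}
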