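#' Walk modes recognised by the package
#'
#' Terrain-defined locomotion categories: level walking, stairs up/down and
#' ramps up/down.
#'
#' @export
WALK_MODES <- c("walk", "stairs_up", "stairs_down", "ramp_up", "ramp_down")

#' Define a walking course
#'
#' A course is an ordered sequence of terrain segments, each walked for a
#' fixed number of steps. Every non-walk segment must be flanked by level-walk
#' segments, and every segment must be long enough (>= 13 steps) that a
#' 6+6-step transition window plus baseline exclusions can be realised inside
#' it. One walk segment is designated as the level-walk baseline segment from
#' which per-participant empirical baselines are computed.
#'
#' @param modes character vector of walk modes, one per segment.
#' @param n_steps integer vector, number of steps per segment.
#' @param baseline_segment index of the designated baseline segment; must be a
#'   "walk" segment. Defaults to the longest walk segment.
#' @return an object of class `course_spec`.
#' @export
course_spec <- function(modes, n_steps, baseline_segment = NULL) {
  modes <- as.character(modes)
  n_steps <- as.integer(n_steps)
  if (length(modes) != length(n_steps))
    stop("modes and n_steps must have equal length")
  bad <- setdiff(modes, WALK_MODES)
  if (length(bad) > 0)
    stop("unknown walk mode(s): ", paste(bad, collapse = ", "))
  if (any(n_steps < 13)) {
    i <- which(n_steps < 13)[1]
    stop(sprintf("segment %d (%s) has %d steps; every segment needs >= 13",
                 i, modes[i], n_steps[i]))
  }
  nonwalk <- which(modes != "walk")
  for (i in nonwalk) {
    left_ok <- i > 1 && modes[i - 1] == "walk"
    right_ok <- i < length(modes) && modes[i + 1] == "walk"
    if (!left_ok || !right_ok)
      stop(sprintf("non-walk segment %d (%s) must be flanked by walk segments",
                   i, modes[i]))
  }
  if (is.null(baseline_segment)) {
    walks <- which(modes == "walk")
    baseline_segment <- walks[which.max(n_steps[walks])]
  }
  if (length(baseline_segment) != 1 || is.na(baseline_segment) ||
      baseline_segment < 1 || baseline_segment > length(modes))
    stop("baseline_segment subscript out of range")
  if (modes[baseline_segment] != "walk")
    stop("baseline segment must have walk mode 'walk'")
  structure(list(modes = modes, n_steps = n_steps,
                 baseline_segment = as.integer(baseline_segment)),
            class = "course_spec")
}

#' Default walking course
#'
#' An alternating walk/stairs/ramp lap loosely patterned on an urban walking
#' track: level-walk sections interleaved with two stairs-down, two stairs-up
#' and one ramp section of each direction.
#'
#' @param walk_steps steps per level-walk segment.
#' @param terrain_steps steps per non-walk segment.
#' @return a `course_spec`.
#' @export
default_course <- function(walk_steps = 20L, terrain_steps = 15L) {
  modes <- c("walk", "stairs_down", "walk", "stairs_up", "walk", "ramp_down",
             "walk", "stairs_up", "walk", "stairs_down", "walk", "ramp_up",
             "walk")
  n <- ifelse(modes == "walk", walk_steps, terrain_steps)
  course_spec(modes, n, baseline_segment = 3L)
}

#' Planted anticipatory effects for the synthetic generator
#'
#' Describes, per transition category (ordered pair of walk modes), when and
#' how strongly the synthetic gaze and gait signals deviate from level-walk
#' behaviour before the transition:
#' \itemize{
#'   \item `head_onset`/`eye_onset`/`gait_onset`: number of steps before the
#'     transition at which the deviation starts ramping (0 = no anticipation).
#'   \item `head_amplitude`/`eye_amplitude`: pitch deviation (degrees,
#'     negative = downward) reached one step before the transition.
#'   \item `step_length_shift`/`step_period_shift`: dimensionless
#'     (Hof-normalized) gait deviation reached one step before the transition
#'     and held over the entire new terrain segment.
#' }
#' Pre-transition deviations ramp linearly in step index from the current
#' steady-state value to the configured amplitude. Gaze pitch additionally has
#' per-mode steady-state holds (`gaze_holds`), emulating the sustained lowered
#' gaze while on stairs.
#'
#' @param categories data.frame with columns `from`, `to`, `head_onset`,
#'   `eye_onset`, `gait_onset`, `head_amplitude`, `eye_amplitude`,
#'   `step_length_shift`, `step_period_shift`.
#' @param gaze_holds data.frame with columns `mode`, `head`, `eye`:
#'   steady-state pitch deviation (degrees) while walking on that terrain.
#' @param noise list of noise standard deviations: `head_deg`, `eye_deg`
#'   (per-step pitch deviation noise, degrees), `step_length`, `step_period`
#'   (normalized gait noise), `angle_frame_deg` (within-step frame jitter),
#'   `accel` (m/s^2), `gyro` (rad/s), `gaze_xy` (image coordinates).
#' @param knee_phase fraction of the step period at which the swinging leg's
#'   knee-angle maximum is placed (default 0.5).
#' @param seed default random seed used by [generate_session()] when none is
#'   given there.
#' @return an object of class `effect_spec`.
#' @export
effect_spec <- function(categories, gaze_holds = NULL, noise = list(),
                        knee_phase = 0.5, seed = 1L) {
  need <- c("from", "to", "head_onset", "eye_onset", "gait_onset",
            "head_amplitude", "eye_amplitude", "step_length_shift",
            "step_period_shift")
  miss <- setdiff(need, names(categories))
  if (length(miss) > 0)
    stop("categories is missing column(s): ", paste(miss, collapse = ", "))
  ons <- as.matrix(categories[, c("head_onset", "eye_onset", "gait_onset")])
  if (any(ons < 0 | ons > 6)) stop("onsets must lie in [0, 6]")
  amp <- as.matrix(categories[, c("head_amplitude", "eye_amplitude",
                                  "step_length_shift", "step_period_shift")])
  if (any(!is.finite(amp))) stop("amplitudes and shifts must be finite")
  if (is.null(gaze_holds))
    gaze_holds <- data.frame(mode = WALK_MODES, head = 0, eye = 0)
  nz <- list(head_deg = 2, eye_deg = 2, step_length = 0.04,
             step_period = 0.06, angle_frame_deg = 0.3, accel = 0.05,
             gyro = 0.01, gaze_xy = 0.002)
  nz[names(noise)] <- noise
  if (any(unlist(nz) < 0)) stop("noise_sd must be >= 0")
  if (knee_phase <= 0 || knee_phase >= 1) stop("knee_phase must be in (0, 1)")
  structure(list(categories = categories, gaze_holds = gaze_holds,
                 noise = nz, knee_phase = knee_phase, seed = as.integer(seed)),
            class = "effect_spec")
}

#' Default planted effects
#'
#' Anticipation onsets and amplitudes chosen to emulate the qualitative
#' structure of anticipatory gaze/gait behaviour on an urban walking track:
#' head pitch starts lowering up to six steps before entering stairs (peak
#' deviation about -25 to -32 degrees one step before stairs, reached one step
#' before the transition), eye pitch somewhat later and weaker (about -15 to
#' -20 degrees), gait (shorter normalized steps, slightly longer periods)
#' only two to three steps before, and ramps showing little or no effect.
#'
#' @param noise optional overrides of the noise standard deviations, see
#'   [effect_spec()].
#' @param seed default seed stored in the spec.
#' @return an `effect_spec`.
#' @export
default_effects <- function(noise = list(), seed = 1L) {
  cat <- rbind(
    data.frame(from = "walk", to = "stairs_down", head_onset = 5, eye_onset = 5,
               gait_onset = 2, head_amplitude = -32, eye_amplitude = -20,
               step_length_shift = -0.30, step_period_shift = 0.08),
    data.frame(from = "walk", to = "stairs_up", head_onset = 6, eye_onset = 4,
               gait_onset = 2, head_amplitude = -25, eye_amplitude = -15,
               step_length_shift = -0.25, step_period_shift = 0.06),
    data.frame(from = "walk", to = "ramp_down", head_onset = 2, eye_onset = 2,
               gait_onset = 0, head_amplitude = -10, eye_amplitude = -8,
               step_length_shift = 0, step_period_shift = 0),
    data.frame(from = "walk", to = "ramp_up", head_onset = 0, eye_onset = 0,
               gait_onset = 0, head_amplitude = 0, eye_amplitude = 0,
               step_length_shift = 0, step_period_shift = 0),
    data.frame(from = "stairs_down", to = "walk", head_onset = 2, eye_onset = 2,
               gait_onset = 2, head_amplitude = -8, eye_amplitude = -5,
               step_length_shift = 0, step_period_shift = 0),
    data.frame(from = "stairs_up", to = "walk", head_onset = 1, eye_onset = 1,
               gait_onset = 3, head_amplitude = -6, eye_amplitude = -4,
               step_length_shift = 0, step_period_shift = 0),
    data.frame(from = "ramp_down", to = "walk", head_onset = 1, eye_onset = 1,
               gait_onset = 0, head_amplitude = -4, eye_amplitude = -3,
               step_length_shift = 0, step_period_shift = 0),
    data.frame(from = "ramp_up", to = "walk", head_onset = 0, eye_onset = 0,
               gait_onset = 0, head_amplitude = 0, eye_amplitude = 0,
               step_length_shift = 0, step_period_shift = 0))
  holds <- data.frame(
    mode = c("walk", "stairs_down", "stairs_up", "ramp_down", "ramp_up"),
    head = c(0, -18, -12, -5, -2),
    eye = c(0, -10, -8, -3, -1))
  effect_spec(cat, gaze_holds = holds, noise = noise, seed = seed)
}

#' Participant parameters for the synthetic generator
#'
#' @param leg_length leg length L in metres.
#' @param step_length preferred level-walk step length in metres.
#' @param step_period preferred level-walk step period in seconds.
#' @param head_pitch0 resting head pitch in degrees (posture; subtracted again
#'   by the empirical baseline downstream).
#' @param eye_pitch0 resting eye-in-head pitch in degrees.
#' @return a list of class `participant_params`.
#' @export
participant_params <- function(leg_length = 0.9, step_length = 0.70,
                               step_period = 0.55, head_pitch0 = -8,
                               eye_pitch0 = -4) {
  if (leg_length <= 0) stop("leg_length must be > 0")
  if (step_length <= 0 || step_period <= 0)
    stop("step_length and step_period must be > 0")
  structure(list(leg_length = leg_length, step_length = step_length,
                 step_period = step_period, head_pitch0 = head_pitch0,
                 eye_pitch0 = eye_pitch0, g = 9.81),
            class = "participant_params")
}
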