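# File I/O, configuration and the end-to-end pipeline.

FRAME_COLUMNS <- c("timestamp", "left_contact", "right_contact",
                   "foot_l_x", "foot_l_y", "foot_l_z",
                   "foot_r_x", "foot_r_y", "foot_r_z",
                   "knee_l", "knee_r", "hip_l", "hip_r", "ankle_l", "ankle_r",
                   "accel_x", "accel_y", "accel_z",
                   "gyro_x", "gyro_y", "gyro_z",
                   "gaze_x", "gaze_y", "mode_label")
STEP_COLUMNS <- c("index", "foot", "t_start", "t_end", "mode_label", "valid")

#' Write a session to delimited tables
#'
#' Writes `frames.csv` and `steps.csv` (UTF-8, "." decimal, header row) with
#' the documented column schema. Optional direct pitch-angle columns
#' (`eye_pitch`, `head_pitch`) are included when present.
#'
#' @param session a `walk_session` (or a list with `frames` and `steps`).
#' @param dir output directory (created if needed).
#' @return invisibly, the two file paths.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  extra <- intersect(c("eye_pitch", "head_pitch"), names(session$frames))
  fp <- file.path(dir, "frames.csv")
  sp <- file.path(dir, "steps.csv")
  utils::write.csv(session$frames[, c(FRAME_COLUMNS, extra)], fp,
                   row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.csv(session$steps[, STEP_COLUMNS], sp, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(c(frames = fp, steps = sp))
}

#' Read a session from delimited tables
#'
#' Columns are matched by header name (order-independent); missing required
#' columns raise an error naming the column, and non-monotone timestamps are
#' rejected.
#'
#' @param frames_path,steps_path paths to `frames.csv` / `steps.csv`.
#' @return list with typed `frames` and `steps` data.frames.
#' @export
read_session <- function(frames_path, steps_path) {
  frames <- utils::read.csv(frames_path, stringsAsFactors = FALSE,
                            fileEncoding = "UTF-8")
  steps <- utils::read.csv(steps_path, stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8")
  miss_f <- setdiff(FRAME_COLUMNS, names(frames))
  if (length(miss_f) > 0)
    stop("frames file is missing column(s): ", paste(miss_f, collapse = ", "))
  miss_s <- setdiff(STEP_COLUMNS, names(steps))
  if (length(miss_s) > 0)
    stop("steps file is missing column(s): ", paste(miss_s, collapse = ", "))
  if (any(diff(frames$timestamp) <= 0))
    stop("frame timestamps must be strictly increasing")
  steps$valid <- as.logical(steps$valid)
  message(sprintf("read %d frames, %d steps", nrow(frames), nrow(steps)))
  list(frames = frames, steps = steps)
}

#' Pipeline configuration
#'
#' Collects the constants of the full analysis: sampling rate, Butterworth
#' cutoffs (4 Hz head, 8 Hz eye, order 4), the gaze-coordinate map, the
#' baseline segment, the 2-step input window, forecasting horizons, CV
#' settings and seeds.
#'
#' @param fs sampling rate, Hz.
#' @param head_cutoff,eye_cutoff,filter_order Butterworth low-pass settings.
#' @param vfov vertical field of view of the scene camera, degrees.
#' @param baseline_segment baseline segment index (NULL = longest walk run).
#' @param horizons forecasting horizons, steps ahead.
#' @param feature_sets feature sets compared in the forecasting stage.
#' @param k,r,n_trees,max_features CV and classifier settings.
#' @param flip_window label jitter (steps) applied by the simulate stage.
#' @param n_sessions number of synthetic sessions (participants x laps)
#'   pooled by the pipeline.
#' @param categories transition categories carried into the forecasting
#'   stage (NULL = all with enough instances).
#' @param use_raw_gaze derive pitch from IMU + gaze coordinates instead of
#'   the direct angle columns.
#' @param madgwick_beta,madgwick_burn_in raw-path orientation settings.
#' @param seed master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(fs = 60, head_cutoff = 4, eye_cutoff = 8,
                            filter_order = 4, vfov = 82,
                            baseline_segment = NULL, horizons = 1:4,
                            feature_sets = c("gaze", "gait", "both"),
                            k = 10L, r = 10L, n_trees = 200L,
                            max_features = "all", flip_window = 2L,
                            n_sessions = 20L,
                            categories = c("walk – stairs_up",
                                           "walk – stairs_down"),
                            use_raw_gaze = FALSE, madgwick_beta = 0.1,
                            madgwick_burn_in = 2, seed = 1L) {
  num <- c(fs = fs, head_cutoff = head_cutoff, eye_cutoff = eye_cutoff,
           filter_order = filter_order, vfov = vfov, k = k, r = r,
           n_trees = n_trees)
  if (any(num <= 0)) stop("all numeric parameters must be positive")
  if (length(horizons) == 0) stop("horizons must be non-empty")
  if (fs <= 2 * max(head_cutoff, eye_cutoff))
    stop("sampling rate must exceed twice the highest filter cutoff")
  structure(list(fs = fs, head_cutoff = head_cutoff, eye_cutoff = eye_cutoff,
                 filter_order = filter_order, vfov = vfov,
                 baseline_segment = baseline_segment, window = 2L,
                 horizons = as.integer(horizons), feature_sets = feature_sets,
                 k = as.integer(k), r = as.integer(r),
                 n_trees = as.integer(n_trees), max_features = max_features,
                 flip_window = as.integer(flip_window),
                 n_sessions = as.integer(n_sessions), categories = categories,
                 use_raw_gaze = use_raw_gaze, madgwick_beta = madgwick_beta,
                 madgwick_burn_in = madgwick_burn_in,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

.config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(config[order(names(config))]), f)
  unname(tools::md5sum(f))
}

#' Process one session into per-step features
#'
#' Detect and validate steps, refine the walk-mode labels, and compute the
#' per-step feature table.
#'
#' @param frames frame table.
#' @param leg_length participant leg length, m.
#' @param config a [pipeline_config()].
#' @return feature-augmented step table (see [compute_step_features()]).
#' @export
process_session <- function(frames, leg_length, config = pipeline_config()) {
  steps <- detect_steps(frames)
  ref <- refine_walk_mode_labels(frames, steps)
  compute_step_features(ref$frames, ref$steps, leg_length = leg_length,
                        baseline_segment = config$baseline_segment,
                        fs = config$fs, use_raw = config$use_raw_gaze,
                        vfov = config$vfov,
                        head_cutoff = config$head_cutoff,
                        eye_cutoff = config$eye_cutoff,
                        order = config$filter_order,
                        beta = config$madgwick_beta,
                        burn_in = config$madgwick_burn_in)
}

#' Run the full synthetic-study pipeline
#'
#' Executes generate -> corrupt labels -> steps/features -> transitions ->
#' stepwise statistics -> forecasting on `n_sessions` synthetic sessions
#' (pooled as participants/laps) and returns a report bundle. With `out_dir`
#' set, writes `step_features.csv`, `transitions.csv`, `stats_report.csv`,
#' `results.csv`, `summary.csv` and a run manifest (config hash, seed, stage
#' row counts). Reruns with the same configuration are identical.
#'
#' @param config a [pipeline_config()].
#' @param course,effects,participant generator settings.
#' @param out_dir optional output directory.
#' @return list with `features`, `transitions`, `stats`, `earliest`,
#'   `forecast` (per-fold scores), `summary`, `comparisons`, `accounting`,
#'   `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), course = default_course(),
                         effects = default_effects(),
                         participant = participant_params(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- list()
  log_stage <- function(stage, n_in, n_out)
    manifest[[length(manifest) + 1]] <<- data.frame(stage = stage,
                                                    rows_in = n_in,
                                                    rows_out = n_out)
  # stage 1: simulate
  all_feats <- list()
  all_trans <- list()
  n_frames_total <- 0
  for (si in seq_len(config$n_sessions)) {
    ses <- generate_session(course, effects, participant,
                            seed = config$seed + 101L * si)
    ses <- corrupt_labels(ses, flip_window = config$flip_window,
                          seed = config$seed + 211L * si)
    n_frames_total <- n_frames_total + nrow(ses$frames)
    # stage 2: features
    feats <- process_session(ses$frames, participant$leg_length, config)
    feats$session <- si
    all_feats[[si]] <- feats
    # stage 3: transitions
    tr <- extract_transitions(feats, participant_id = si, lap_id = 1L)
    all_trans[[si]] <- tr
  }
  features <- do.call(rbind, all_feats)
  log_stage("simulate", config$n_sessions, n_frames_total)
  log_stage("features", n_frames_total, nrow(features))
  transitions <- do.call(rbind, all_trans)
  transitions$instance <- cumsum(!duplicated(
    interaction(transitions$participant, transitions$instance, drop = TRUE)))
  n_before <- nrow(transitions)
  transitions <- iqr_filter(transitions)
  log_stage("transitions", n_before, nrow(transitions))

  # stage 4: stepwise statistics (categories with too few instances after
  # outlier removal are excluded from testing)
  inst_counts <- table(transitions$category) / 12
  testable <- names(inst_counts)[inst_counts >= 6]
  if (length(testable) == 0)
    stop("stats stage: no transition category has >= 6 instances")
  tr_test <- transitions[transitions$category %in% testable, ]
  variables <- c("dtheta", "dalpha", "dl_norm", "dp_norm")
  stats_report <- do.call(rbind, lapply(variables, function(v)
    pairwise_stepwise_tests(tr_test, v, seed = config$seed)))
  earliest <- do.call(rbind, lapply(split(stats_report,
                                          list(stats_report$category,
                                               stats_report$variable),
                                          drop = TRUE), function(res)
    data.frame(category = res$category[1], variable = res$variable[1],
               earliest_step = earliest_significant_step(res))))
  rownames(earliest) <- NULL
  log_stage("stats", nrow(transitions), nrow(stats_report))

  # stage 5: forecasting
  counts <- table(transitions$category) / 12
  cats <- config$categories
  if (is.null(cats)) cats <- names(counts)[counts >= config$k]
  cats <- intersect(cats, names(counts)[counts >= config$k])
  forecast <- list()
  summary_rows <- list()
  comp_rows <- list()
  for (cat in cats) {
    sub <- transitions[transitions$category == cat, ]
    for (h in config$horizons) {
      sets <- list()
      for (fsname in config$feature_sets) {
        ds <- build_forecast_dataset(sub, h, fsname)
        cfg <- cv_config(k = config$k, r = config$r, seed = config$seed,
                         n_trees = config$n_trees,
                         max_features = config$max_features)
        sc <- repeated_cv_evaluate(ds, cfg)
        sets[[fsname]] <- sc
        forecast[[length(forecast) + 1]] <- data.frame(
          category = cat, horizon = h, feature_set = fsname,
          fold = seq_along(sc), mcc = as.numeric(sc))
        ci <- bootstrap_ci(as.numeric(sc), n_boot = 2000,
                           seed = config$seed + h)
        summary_rows[[length(summary_rows) + 1]] <- data.frame(
          category = cat, horizon = h, feature_set = fsname,
          mean_mcc = mean(sc), ci_lower = ci[1], ci_upper = ci[2])
      }
      pairs <- utils::combn(names(sets), 2, simplify = FALSE)
      for (pr in pairs) {
        ct <- corrected_cv_ttest(sets[[pr[1]]], sets[[pr[2]]],
                                 k = config$k, r = config$r)
        comp_rows[[length(comp_rows) + 1]] <- data.frame(
          category = cat, horizon = h, model_a = pr[1], model_b = pr[2],
          mean_diff = ct$mean_diff, t = ct$t, p = ct$p, df = ct$df)
      }
    }
  }
  forecast <- do.call(rbind, forecast)
  summary <- do.call(rbind, summary_rows)
  comparisons <- do.call(rbind, comp_rows)
  log_stage("forecast", nrow(transitions),
            if (is.null(forecast)) 0L else nrow(forecast))

  manifest <- do.call(rbind, manifest)
  manifest$config_hash <- .config_hash(unclass(config))
  manifest$seed <- config$seed
  manifest$package_version <- as.character(utils::packageVersion("gaitgaze"))

  bundle <- list(features = features, transitions = transitions,
                 stats = stats_report, earliest = earliest,
                 forecast = forecast, summary = summary,
                 comparisons = comparisons,
                 accounting = step_accounting(features),
                 manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(x, f) utils::write.csv(
      cbind(x, config_hash = manifest$config_hash[1]),
      file.path(out_dir, f), row.names = FALSE, fileEncoding = "UTF-8")
    wr(features, "step_features.csv")
    wr(transitions, "transitions.csv")
    wr(stats_report, "stats_report.csv")
    wr(forecast, "results.csv")
    wr(summary, "summary.csv")
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE, fileEncoding = "UTF-8")
  }
  bundle
}
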