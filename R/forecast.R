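# Step-ahead transition forecasting: 2-step feature windows, SMOTE class
# balancing, random-forest classification under repeated stratified k-fold
# cross-validation, Matthews' correlation coefficient, and the corrected
# repeated k-fold CV t-test for model comparisons.

#' Feature sets for the forecasting task
#'
#' @param set "gaze" (head/eye/gaze pitch deviations), "gait" (normalized
#'   step length/period deviations) or "both".
#' @return character vector of feature column names.
#' @export
feature_set_vars <- function(set = c("gaze", "gait", "both")) {
  set <- match.arg(set)
  switch(set,
         gaze = c("dalpha", "dtheta", "dgamma"),
         gait = c("dl_norm", "dp_norm"),
         both = c("dalpha", "dtheta", "dgamma", "dl_norm", "dp_norm"))
}

#' Build the step-ahead forecasting dataset
#'
#' For each transition instance, a window of two consecutive steps slides over
#' the six pre-transition steps (-6..-1), giving five windows with end
#' positions -5..-1. The feature vector stacks the chosen variables over the
#' window, oldest step first; the label is 1 iff the transition occurs exactly
#' `horizon` steps after the window's last step (window end at step
#' `-horizon`). Windows with missing features are skipped.
#'
#' @param transitions long instance table from [extract_transitions()].
#' @param horizon forecasting horizon s in steps (1..4).
#' @param feature_set "gaze", "gait" or "both".
#' @return data.frame with `label` (factor 0/1), `instance`, `window_end`, and
#'   stacked feature columns `<var>_lag1` (older step), `<var>_lag0`.
#' @export
build_forecast_dataset <- function(transitions, horizon,
                                   feature_set = c("gaze", "gait", "both")) {
  horizon <- as.integer(horizon)
  if (horizon < 1 || horizon > 4) stop("horizon must be in 1..4")
  vars <- feature_set_vars(match.arg(feature_set))
  pre <- transitions[transitions$rel_index < 0, ]
  key <- interaction(pre$category, pre$participant, pre$lap, pre$instance,
                     drop = TRUE)
  out <- list()
  for (id in levels(key)) {
    w <- pre[key == id, ]
    w <- w[order(w$rel_index), ]
    if (nrow(w) != 6) next
    for (e in -5:-1) {
      older <- w[w$rel_index == e - 1, vars]
      newer <- w[w$rel_index == e, vars]
      x <- c(unlist(older), unlist(newer))
      if (any(is.na(x))) next
      row <- as.data.frame(as.list(x))
      names(row) <- c(paste0(vars, "_lag1"), paste0(vars, "_lag0"))
      row$label <- if (e == -horizon) 1L else 0L
      row$instance <- id
      row$window_end <- e
      out[[length(out) + 1]] <- row
    }
  }
  if (length(out) == 0) stop("no complete windows")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$label <- factor(res$label, levels = c(0, 1))
  res
}

#' SMOTE class balancing
#'
#' Augments the minority class with synthetic points interpolated between a
#' minority sample and one of its k nearest minority neighbours (uniform
#' interpolation weight), up to 50% of the majority count, then randomly
#' downsamples the majority class to a 1:1 ratio.
#'
#' @param x numeric feature matrix (or data.frame of numeric columns).
#' @param y binary labels (factor or 0/1), both classes present.
#' @param k number of minority nearest neighbours considered.
#' @param seed seed for reproducibility.
#' @return list with balanced `x` (matrix), `y` (factor), and `synthetic`
#'   (logical flag per row).
#' @export
smote_balance <- function(x, y, k = 5, seed = 1L) {
  x <- as.matrix(x)
  y <- factor(y)
  tab <- table(y)
  if (length(tab) < 2 || any(tab == 0)) stop("both classes must be present")
  set.seed(as.integer(seed))
  ord <- order(tab)  # ties: first level is treated as the minority
  min_cl <- names(tab)[ord[1]]
  maj_cl <- names(tab)[ord[2]]
  xm <- x[y == min_cl, , drop = FALSE]
  xM <- x[y == maj_cl, , drop = FALSE]
  n_min <- nrow(xm); n_maj <- nrow(xM)
  if (n_min < 2) stop("minority class needs at least 2 samples for SMOTE")
  target <- ceiling(0.5 * n_maj)
  synth <- NULL
  if (n_min < target) {
    n_new <- target - n_min
    kk <- min(k, n_min - 1)
    d2 <- as.matrix(stats::dist(xm))^2
    diag(d2) <- Inf
    nn <- t(apply(d2, 1, function(r) order(r)[seq_len(kk)]))
    base <- rep_len(seq_len(n_min), n_new)
    pick <- nn[cbind(base, sample.int(kk, n_new, replace = TRUE))]
    u <- stats::runif(n_new)
    synth <- xm[base, , drop = FALSE] +
      u * (xm[pick, , drop = FALSE] - xm[base, , drop = FALSE])
  }
  n_min_new <- max(n_min, target)
  keep_maj <- sample.int(n_maj, min(n_maj, n_min_new))
  xb <- rbind(xm, synth, xM[keep_maj, , drop = FALSE])
  yb <- factor(c(rep(min_cl, n_min_new), rep(maj_cl, length(keep_maj))),
               levels = levels(y))
  list(x = xb, y = yb,
       synthetic = c(rep(FALSE, n_min), rep(TRUE, n_min_new - n_min),
                     rep(FALSE, length(keep_maj))))
}

#' Matthews' correlation coefficient
#'
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, in [-1, 1]:
#' +1 for perfect prediction, -1 for complete disagreement, 0 for chance. When
#' any factor of the denominator is zero the value is defined as 0.
#'
#' @param tp,tn,fp,fn confusion-matrix counts (non-negative).
#' @return MCC value.
#' @export
mcc <- function(tp, tn, fp, fn) {
  counts <- c(tp, tn, fp, fn)
  if (any(is.na(counts)) || any(counts < 0))
    stop("confusion counts must be non-negative")
  if (sum(counts) == 0) stop("confusion matrix is empty")
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Cross-validation configuration
#'
#' @param k number of stratified folds.
#' @param r number of repeats.
#' @param seed master seed; per-repeat seeds are derived by fixed offsets.
#' @param n_trees random-forest size.
#' @param max_features "all" (every feature candidate at each split) or
#'   "sqrt".
#' @param smote apply SMOTE balancing inside the training folds.
#' @param smote_k SMOTE neighbour count.
#' @return list of class `cv_config`.
#' @export
cv_config <- function(k = 10L, r = 10L, seed = 1L, n_trees = 200L,
                      max_features = c("all", "sqrt"), smote = TRUE,
                      smote_k = 5L) {
  if (k < 2) stop("k must be >= 2")
  if (r < 1) stop("r must be >= 1")
  structure(list(k = as.integer(k), r = as.integer(r),
                 seed = as.integer(seed), n_trees = as.integer(n_trees),
                 max_features = match.arg(max_features), smote = smote,
                 smote_k = as.integer(smote_k)),
            class = "cv_config")
}

#' Stratified fold assignment
#'
#' Shuffles within each class and deals fold ids round-robin, preserving the
#' class distribution per fold.
#'
#' @param y class labels.
#' @param k number of folds.
#' @param seed seed.
#' @return integer fold id per observation.
#' @export
stratified_folds <- function(y, k, seed = 1L) {
  y <- factor(y)
  if (any(table(y) < k))
    stop(sprintf("smallest class has %d observation(s); cannot stratify into %d folds",
                 min(table(y)), k))
  set.seed(as.integer(seed))
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

.confusion <- function(truth, pred) {
  truth <- factor(truth, levels = c(0, 1))
  pred <- factor(pred, levels = c(0, 1))
  tab <- table(truth, pred)
  list(tp = tab["1", "1"], tn = tab["0", "0"],
       fp = tab["0", "1"], fn = tab["1", "0"])
}

.fit_predict_rf <- function(x_train, y_train, x_test, n_trees, max_features,
                            seed) {
  mtry <- if (max_features == "all") ncol(x_train)
          else max(1L, floor(sqrt(ncol(x_train))))
  df <- as.data.frame(x_train)
  df$.label <- y_train
  fit <- ranger::ranger(dependent.variable.name = ".label", data = df,
                        num.trees = n_trees, mtry = mtry, seed = seed,
                        num.threads = 1, verbose = FALSE)
  stats::predict(fit, data = as.data.frame(x_test),
                 num.threads = 1)$predictions
}

#' Repeated stratified cross-validated MCC of a random forest
#'
#' For each repeat, the data are shuffled into k stratified folds; per fold, a
#' random forest is trained on the remaining folds (with SMOTE applied to the
#' training portion only) and evaluated by MCC on the untouched test fold.
#' Fold assignments depend only on the labels and the seed, so models
#' evaluated with the same seed share identical folds (no leakage in paired
#' comparisons). Identical seeds give identical scores.
#'
#' @param data data.frame from [build_forecast_dataset()] (`label` plus
#'   feature columns; `instance`/`window_end` are ignored as features).
#' @param config a [cv_config()].
#' @return numeric vector of k*r MCC scores, with the per-repeat fold
#'   assignments in attribute `"folds"` and test-fold sizes in `"test_sizes"`.
#' @export
repeated_cv_evaluate <- function(data, config = cv_config()) {
  y <- data$label
  drop_cols <- intersect(c("label", "instance", "window_end"), names(data))
  x <- as.matrix(data[, setdiff(names(data), drop_cols), drop = FALSE])
  scores <- numeric(0)
  fold_log <- list()
  test_sizes <- integer(0)
  for (rep_i in seq_len(config$r)) {
    rep_seed <- config$seed + 7919L * rep_i
    fold <- stratified_folds(y, config$k, seed = rep_seed)
    fold_log[[rep_i]] <- fold
    for (f in seq_len(config$k)) {
      tr <- fold != f
      if (config$smote) {
        bal <- smote_balance(x[tr, , drop = FALSE], y[tr],
                             k = config$smote_k, seed = rep_seed + f)
        x_tr <- bal$x; y_tr <- bal$y
      } else {
        x_tr <- x[tr, , drop = FALSE]; y_tr <- y[tr]
      }
      pred <- .fit_predict_rf(x_tr, y_tr, x[!tr, , drop = FALSE],
                              config$n_trees, config$max_features,
                              seed = rep_seed + 1000L + f)
      cm <- .confusion(y[!tr], pred)
      scores <- c(scores, mcc(cm$tp, cm$tn, cm$fp, cm$fn))
      test_sizes <- c(test_sizes, sum(!tr))
    }
  }
  attr(scores, "folds") <- fold_log
  attr(scores, "test_sizes") <- test_sizes
  scores
}

#' Corrected repeated k-fold CV t-test
#'
#' Paired t-test on fold-score differences with the Nadeau–Bengio variance
#' correction: `t = mean(d) / sqrt((1/(k r) + rho) var(d))` with
#' `rho = n_test / n_train = 1/(k-1)`, two-sided p from Student's t with
#' `df = k r - 1`.
#'
#' @param scores_a,scores_b paired fold scores of the two models (length k*r,
#'   same fold order).
#' @param k,r fold count and repeat count.
#' @return list with `t`, `p`, `df`, `mean_diff`.
#' @export
corrected_cv_ttest <- function(scores_a, scores_b, k = 10L, r = 10L) {
  n <- k * r
  if (length(scores_a) != n || length(scores_b) != n)
    stop("scores must have length k*r and be paired by fold")
  d <- as.numeric(scores_a) - as.numeric(scores_b)
  rho <- 1 / (k - 1)
  vd <- stats::var(d)
  m <- mean(d)
  if (vd == 0) {
    if (m == 0) return(list(t = 0, p = 1, df = n - 1, mean_diff = 0))
    return(list(t = sign(m) * Inf, p = 0, df = n - 1, mean_diff = m))
  }
  t_stat <- m / sqrt((1 / n + rho) * vd)
  p <- 2 * stats::pt(-abs(t_stat), df = n - 1)
  list(t = t_stat, p = p, df = n - 1, mean_diff = m)
}

#' Hyperparameter grid search with shared folds
#'
#' Evaluates every random-forest configuration on every supplied dataset with
#' identical CV folds (fold assignment depends only on labels and seed, not on
#' the configuration) and selects the configuration with the highest mean MCC
#' across all datasets.
#'
#' @param datasets named list of forecasting datasets (conditions: transition
#'   categories x horizons x feature sets).
#' @param grid data.frame with columns `n_trees`, `max_features`; defaults to
#'   trees in {10, 20, 100, 200, 300, 500} crossed with {"sqrt", "all"}.
#' @param k,r,seed CV settings shared by all configurations.
#' @return list with `best` (row of the grid), `scores` (long data.frame of
#'   mean MCC per config and dataset).
#' @export
grid_search <- function(datasets,
                        grid = expand.grid(
                          n_trees = c(10L, 20L, 100L, 200L, 300L, 500L),
                          max_features = c("sqrt", "all"),
                          stringsAsFactors = FALSE),
                        k = 10L, r = 10L, seed = 1L) {
  if (nrow(grid) == 0) stop("grid must be non-empty")
  rows <- list()
  for (g in seq_len(nrow(grid))) {
    cfg <- cv_config(k = k, r = r, seed = seed, n_trees = grid$n_trees[g],
                     max_features = grid$max_features[g])
    for (nm in names(datasets)) {
      sc <- repeated_cv_evaluate(datasets[[nm]], cfg)
      rows[[length(rows) + 1]] <- data.frame(
        config = g, n_trees = grid$n_trees[g],
        max_features = grid$max_features[g], dataset = nm,
        mean_mcc = mean(sc))
    }
  }
  scores <- do.call(rbind, rows)
  overall <- tapply(scores$mean_mcc, scores$config, mean)
  best <- grid[as.integer(names(which.max(overall))), , drop = FALSE]
  list(best = best, scores = scores)
}
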