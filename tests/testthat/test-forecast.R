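test_that("each instance yields five 2-step windows with one positive per horizon", {
  tr <- extract_transitions(transition_step_table())
  for (h in 1:4) {
    ds <- build_forecast_dataset(tr, h, "both")
    expect_equal(nrow(ds), 5)
    expect_equal(sort(ds$window_end), -5:-1)
    expect_equal(sum(ds$label == 1), 1)
    expect_equal(ds$window_end[ds$label == 1], -h)
  }
  # feature arity: 2 steps x |variable set|
  feat_cols <- function(d) setdiff(names(d), c("label", "instance",
                                               "window_end"))
  expect_length(feat_cols(build_forecast_dataset(tr, 1, "both")), 10)
  expect_length(feat_cols(build_forecast_dataset(tr, 1, "gait")), 4)
  expect_length(feat_cols(build_forecast_dataset(tr, 1, "gaze")), 6)
  # stacking is oldest-first: lag1 columns hold the older step's value
  ds <- build_forecast_dataset(tr, 1, "gait")
  w <- ds[ds$window_end == -3, ]
  expect_equal(w$dl_norm_lag1, tr$dl_norm[tr$rel_index == -4])
  expect_equal(w$dl_norm_lag0, tr$dl_norm[tr$rel_index == -3])
})

test_that("MCC endpoints and zero-denominator convention hold", {
  expect_equal(mcc(30, 70, 0, 0), 1)
  expect_equal(mcc(0, 0, 70, 30), -1)
  expect_equal(mcc(25, 25, 25, 25), 0)
  expect_equal(mcc(10, 0, 0, 5), 0)  # a zero denominator factor
  expect_error(mcc(-1, 2, 3, 4), "non-negative")
})

test_that("MCC equals the phi correlation of prediction and truth vectors", {
  set.seed(33)
  for (i in 1:1000) {
    cnt <- sample(0:40, 4, replace = TRUE)
    if (sum(cnt) == 0) next
    truth <- rep(c(1, 1, 0, 0), cnt)      # tp, fn, fp, tn
    pred <- rep(c(1, 0, 1, 0), cnt)
    oracle <- suppressWarnings(cor(truth, pred))
    if (is.na(oracle)) oracle <- 0        # zero-variance convention
    expect_equal(mcc(cnt[1], cnt[4], cnt[3], cnt[2]), oracle,
                 tolerance = 1e-12)
  }
})

test_that("SMOTE balances 10/90 to 45/45 with interpolated minority points", {
  set.seed(2)
  x <- rbind(matrix(rnorm(10 * 3, 5), ncol = 3),
             matrix(rnorm(90 * 3, 0), ncol = 3))
  y <- rep(c(1, 0), c(10, 90))
  bal <- smote_balance(x, y, seed = 4)
  expect_equal(as.vector(table(bal$y)), c(45, 45))
  expect_equal(nrow(bal$x), 90)
  # synthetic points lie componentwise between two original minority points
  synth <- bal$x[bal$synthetic, , drop = FALSE]
  orig <- x[y == 1, , drop = FALSE]
  for (i in seq_len(nrow(synth))) {
    lo <- apply(orig, 2, min); hi <- apply(orig, 2, max)
    expect_true(all(synth[i, ] >= lo - 1e-12 & synth[i, ] <= hi + 1e-12))
  }
  expect_true(all(!bal$synthetic[bal$y == 0]))
  # determinism and error handling
  bal2 <- smote_balance(x, y, seed = 4)
  expect_identical(bal$x, bal2$x)
  expect_error(smote_balance(x, rep(0, 100)), "both classes")
})

test_that("repeated stratified CV returns k*r seeded scores with intact test folds", {
  tr <- do.call(rbind, lapply(1:12, function(i)
    extract_transitions(transition_step_table(seed = 700 + i),
                        participant_id = i)))
  ds <- build_forecast_dataset(tr, 1, "both")
  cfg <- cv_config(k = 4, r = 3, seed = 5, n_trees = 50)
  sc1 <- repeated_cv_evaluate(ds, cfg)
  expect_length(sc1, 12)
  sc2 <- repeated_cv_evaluate(ds, cfg)
  expect_equal(as.numeric(sc1), as.numeric(sc2))
  # every observation is tested exactly once per repeat; test folds untouched
  expect_equal(sum(attr(sc1, "test_sizes")), 3 * nrow(ds))
  for (fold in attr(sc1, "folds"))
    expect_equal(sort(unique(fold)), 1:4)
  expect_error(stratified_folds(rep(c(0, 1), c(30, 3)), k = 5),
               "cannot stratify")
})

test_that("the classifier separates separable data and is at chance on shuffled labels", {
  set.seed(14)
  n <- 120
  x <- data.frame(a = c(rnorm(n / 2, 3), rnorm(n / 2, -3)),
                  b = rnorm(n))
  x$label <- factor(rep(c(1, 0), each = n / 2))
  cfg <- cv_config(k = 10, r = 2, seed = 9, n_trees = 100)
  expect_gte(mean(repeated_cv_evaluate(x, cfg)), 0.95)
  x$label <- sample(x$label)
  expect_lt(abs(mean(repeated_cv_evaluate(x, cfg))), 0.1)
})

test_that("corrected repeated k-fold CV test behaves at its boundaries", {
  s <- rnorm(100)
  res <- corrected_cv_ttest(s, s, k = 10, r = 10)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  expect_equal(res$df, 99)
  res2 <- corrected_cv_ttest(rep(0.6, 100), rep(0.5, 100), k = 10, r = 10)
  expect_equal(res2$p, 0)
  expect_error(corrected_cv_ttest(rnorm(50), rnorm(100), k = 10, r = 10),
               "length")
})

test_that("grid search shares folds across configurations and picks the winner", {
  tr <- do.call(rbind, lapply(1:12, function(i)
    extract_transitions(transition_step_table(seed = 800 + i),
                        participant_id = i)))
  ds <- build_forecast_dataset(tr, 1, "both")
  grid1 <- data.frame(n_trees = 50L, max_features = "all",
                      stringsAsFactors = FALSE)
  g1 <- grid_search(list(h1 = ds), grid = grid1, k = 4, r = 2, seed = 3)
  expect_equal(g1$best$n_trees, 50L)
  # fold assignments are identical across configs (leakage audit)
  f_a <- attr(repeated_cv_evaluate(ds, cv_config(4, 2, seed = 3,
                                                 n_trees = 10)), "folds")
  f_b <- attr(repeated_cv_evaluate(ds, cv_config(4, 2, seed = 3,
                                                 n_trees = 300,
                                                 max_features = "sqrt")),
              "folds")
  expect_identical(f_a, f_b)
  # a dominant configuration wins: weak signal, 1 tree vs 200 trees
  set.seed(15)
  x <- data.frame(a = c(rnorm(60, 1), rnorm(60, -1)), b = rnorm(120),
                  c = rnorm(120), d = rnorm(120),
                  label = factor(rep(c(1, 0), each = 60)))
  g2 <- grid_search(list(d = x),
                    grid = data.frame(n_trees = c(1L, 200L),
                                      max_features = "all",
                                      stringsAsFactors = FALSE),
                    k = 4, r = 2, seed = 8)
  expect_equal(g2$best$n_trees, 200L)
})
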