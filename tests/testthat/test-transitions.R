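test_that("1-NN label refinement matches an exhaustive distance scan", {
  set.seed(42)
  ref <- matrix(rnorm(50 * 6), 50, 6)
  query <- matrix(rnorm(20 * 6), 20, 6)
  got <- gaitgaze:::.nn1(query, ref, chunk = 7L)
  want <- apply(query, 1, function(q)
    which.min(colSums((t(ref) - q)^2)))
  expect_equal(got, unname(want))
})

test_that("jittered boundaries are restored to within one step of ground truth", {
  n_cases <- 0; n_ok <- 0; n_exact <- 0
  for (seed in 1:9) {
    ses <- generate_session(default_course(), default_effects(),
                            participant_params(), seed = 200 + seed)
    cor <- corrupt_labels(ses, flip_window = 2, seed = 300 + seed)
    steps <- detect_steps(cor$frames)
    ref <- refine_walk_mode_labels(cor$frames, steps)
    lab <- ref$steps$mode_label
    found <- which(lab[-1] != lab[-length(lab)])
    for (b in ses$transitions$step_index) {
      n_cases <- n_cases + 1
      d <- min(abs(found - b))
      n_ok <- n_ok + (d <= 1)
      n_exact <- n_exact + (d == 0)
    }
  }
  expect_gte(n_cases, 100)
  expect_gte(n_ok / n_cases, 0.9)
})

test_that("frames identical to an interior frame adopt its label", {
  ses <- generate_session(default_course(), default_effects(),
                          participant_params(), seed = 77)
  cor <- corrupt_labels(ses, flip_window = 2, seed = 78)
  fr <- cor$frames
  steps <- detect_steps(fr)
  # copy the joint angles of an interior stairs_down frame onto a frame right
  # at a walk -> stairs_down boundary
  b <- ses$transitions$step_index[ses$transitions$to == "stairs_down"][1]
  interior_step <- ses$steps[ses$steps$mode_label == "stairs_down" &
                               ses$steps$segment ==
                                 ses$steps$segment[b + 1], ]
  donor_t <- interior_step$t_start[7]
  donor <- which(fr$timestamp >= donor_t)[1]
  target <- which(fr$timestamp >= ses$steps$t_start[b + 1])[1]
  cols <- c("hip_l", "hip_r", "knee_l", "knee_r", "ankle_l", "ankle_r")
  fr[target, cols] <- fr[donor, cols]
  ref <- refine_walk_mode_labels(fr, steps)
  expect_equal(ref$steps$mode_label[findInterval(fr$timestamp[target],
                                                 ref$steps$t_start)],
               "stairs_down")
})

test_that("a clean 12-step window around a label change yields one instance", {
  st <- transition_step_table()
  tr <- extract_transitions(st)
  expect_equal(length(unique(tr$instance)), 1)
  expect_equal(tr$rel_index, c(-6:-1, 1:6))
  expect_equal(unique(tr$category), "walk – stairs_up")
  # boundary labels consistent with the category
  b <- tr$boundary_step[1]
  expect_equal(st$mode_label[b], "walk")
  expect_equal(st$mode_label[b + 1], "stairs_up")
})

test_that("an invalid step inside the window discards the instance", {
  st <- transition_step_table()
  st$valid[st$index == 13] <- FALSE  # relative step -3 (boundary after 15)
  expect_equal(nrow(extract_transitions(st)), 0)
  st2 <- transition_step_table()
  st2$dalpha[st2$index == 18] <- NA  # missing feature at +3
  expect_equal(nrow(extract_transitions(st2)), 0)
})

test_that("20 participants x 3 laps x 1 occurrence give 60 observations", {
  all_tr <- list()
  for (p in 1:20) for (lap in 1:3) {
    st <- transition_step_table(seed = p * 100 + lap)
    all_tr[[length(all_tr) + 1]] <-
      extract_transitions(st, participant_id = p, lap_id = lap)
  }
  tr <- do.call(rbind, all_tr)
  key <- interaction(tr$participant, tr$lap, tr$instance, drop = TRUE)
  expect_equal(length(levels(key)), 60)
  expect_equal(nrow(tr), 60 * 12)
})

test_that("transitions closer than 12 steps are both discarded", {
  st <- transition_step_table(n_before = 19, n_after = 19)
  st$mode_label <- rep(c("walk", "stairs_up", "walk"), c(15, 8, 15))
  expect_warning(tr <- extract_transitions(st), "overlapping")
  expect_equal(nrow(tr), 0)
})

test_that("IQR filtering removes only instances with out-of-fence cells", {
  grid <- seq(-0.005, 0.005, length.out = 10)  # bounded, outlier-free jitter
  mk <- function(n, jitter = FALSE) {
    do.call(rbind, lapply(seq_len(n), function(i) {
      st <- transition_step_table(seed = 1)  # identical features
      tr <- extract_transitions(st, participant_id = i)
      if (jitter)
        for (v in c("dl_norm", "dp_norm", "dtheta", "dalpha", "dgamma"))
          tr[[v]] <- tr[[v]] + grid[i]
      tr
    }))
  }
  ident <- mk(8)
  expect_equal(nrow(iqr_filter(ident)), nrow(ident))  # IQR = 0, none removed

  jit <- mk(10, jitter = TRUE)
  out <- jit
  out$dalpha[out$participant == 4 & out$rel_index == 2] <-
    out$dalpha[out$participant == 4 & out$rel_index == 2] + 10
  kept <- iqr_filter(out)
  expect_false(4 %in% kept$participant)
  expect_equal(sort(unique(kept$participant)), setdiff(1:10, 4))
})

test_that("IQR flags match a brute-force per-cell quartile scan", {
  set.seed(9)
  tr <- do.call(rbind, lapply(1:10, function(i) {
    st <- transition_step_table(seed = 500 + i)
    extract_transitions(st, participant_id = i)
  }))
  kept <- iqr_filter(tr)
  vars <- c("dl_norm", "dp_norm", "dtheta", "dalpha", "dgamma")
  flagged <- c()
  for (v in vars) for (ri in unique(tr$rel_index)) {
    x <- tr[[v]][tr$rel_index == ri]
    pid <- tr$participant[tr$rel_index == ri]
    q <- quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    flagged <- union(flagged, pid[x < q[1] - 1.5 * iqr | x > q[2] + 1.5 * iqr])
  }
  expect_equal(sort(unique(kept$participant)), sort(setdiff(1:10, flagged)))
})

test_that("small categories pass through the IQR filter with a warning", {
  tr <- do.call(rbind, lapply(1:3, function(i)
    extract_transitions(transition_step_table(seed = i), participant_id = i)))
  expect_warning(out <- iqr_filter(tr), "< 4")
  expect_equal(nrow(out), nrow(tr))
})
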