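test_that("alternating contacts with mid-step knee maxima give valid steps", {
  ev <- data.frame(t = c(0.5, 1.0, 1.5), foot = c("left", "right", "left"))
  steps <- detect_steps(mini_frames(ev, knee_phase = 0.5))
  expect_equal(nrow(steps), 2)
  expect_equal(steps$foot, c("left", "right"))
  expect_true(all(steps$valid))
  expect_equal(steps$t_start, c(0.5, 1.0))
  expect_equal(steps$t_end, c(1.0, 1.5))
})

test_that("a repeated-foot contact invalidates the affected step", {
  ev <- data.frame(t = c(0.5, 1.0, 1.5, 2.0),
                   foot = c("left", "right", "left", "left"))
  steps <- detect_steps(mini_frames(ev))
  expect_equal(steps$valid, c(TRUE, TRUE, FALSE))
})

test_that("knee maxima outside the central 10-90% of the step invalidate it", {
  ev <- alternating_events(4)
  late <- detect_steps(mini_frames(ev, knee_phase = c(0.5, 0.95, 0.5)))
  expect_equal(late$valid, c(TRUE, FALSE, TRUE))
  early <- detect_steps(mini_frames(ev, knee_phase = c(0.05, 0.5, 0.5)))
  expect_equal(early$valid, c(FALSE, TRUE, TRUE))
})

test_that("simultaneous contacts of both feet invalidate adjacent steps", {
  fr <- mini_frames(alternating_events(4))
  k <- round(1.0 * 60) + 1  # second event frame: add a left contact too
  fr$left_contact[k] <- 1L
  steps <- detect_steps(fr)
  expect_false(steps$valid[1])
  expect_false(steps$valid[2])
})

test_that("degenerate inputs are handled explicitly", {
  fr <- mini_frames(alternating_events(2))
  fr$left_contact[] <- 0L; fr$right_contact[] <- 0L
  expect_warning(empty <- detect_steps(fr), "no foot contacts")
  expect_equal(nrow(empty), 0)
  fr2 <- mini_frames(alternating_events(3))
  fr2$timestamp[10] <- fr2$timestamp[12]
  expect_error(detect_steps(fr2), "strictly increasing")
})

test_that("step length is the 3-D distance between opposite-foot contact positions", {
  ev <- data.frame(t = c(0.50, 1.05), foot = c("left", "right"))
  fr <- mini_frames(ev)
  fr$foot_r_x[] <- 0.3
  fr$foot_r_y[] <- 0.4
  steps <- step_metrics(detect_steps(fr), fr)
  expect_equal(steps$l, 0.5)       # 3-4-5 triangle
  expect_equal(steps$p, 0.55)
  fr$foot_l_x[] <- 0.7; fr$foot_r_x[] <- 1.4; fr$foot_r_y[] <- 0
  expect_equal(step_metrics(detect_steps(fr), fr)$l, 0.7)
  fr$foot_r_x[] <- NA
  miss <- step_metrics(detect_steps(fr), fr)
  expect_false(miss$valid[1])
})

test_that("Hof normalization is dimensionless and rejects bad leg lengths", {
  expect_equal(hof_normalize(0.9, 0.5, 0.9)$l_norm, 1.0)
  expect_equal(hof_normalize(0.72, 0.5, 0.90)$l_norm, 0.8)
  expect_equal(hof_normalize(0.5, 0.31623, 0.981)$p_norm, 1.0,
               tolerance = 1e-4)
  expect_error(hof_normalize(0.7, 0.5, 0), "L must be > 0")
})

test_that("gait baseline excludes six steps on both ends of the segment", {
  set.seed(4)
  steps <- data.frame(l_norm = runif(20, 0.6, 1.0),
                      p_norm = runif(20, 1.5, 2.1), valid = TRUE)
  bl <- gait_baseline(steps)
  expect_equal(bl$l0, mean(steps$l_norm[7:14]))   # brute-force oracle
  expect_equal(bl$p0, mean(steps$p_norm[7:14]))
  expect_error(gait_baseline(steps[1:12, ]), "12")
  # constant segment gives that constant
  const <- data.frame(l_norm = rep(0.8, 20), p_norm = rep(1.8, 20),
                      valid = TRUE)
  expect_equal(gait_baseline(const)$l0, 0.8)
  # invalid interior steps are excluded from the mean
  steps2 <- steps
  steps2$valid[8] <- FALSE
  expect_equal(gait_baseline(steps2)$l0, mean(steps$l_norm[c(7, 9:14)]))
})

test_that("gait deviations equal elementwise differences from the baseline", {
  set.seed(8)
  steps <- data.frame(l_norm = rnorm(30, 0.8, 0.1),
                      p_norm = rnorm(30, 1.8, 0.1))
  out <- gait_deviations(steps, list(l0 = 0.80, p0 = 1.75))
  expect_equal(out$dl_norm, steps$l_norm - 0.80)
  expect_equal(out$dp_norm, steps$p_norm - 1.75)
  expect_equal(gait_deviations(data.frame(l_norm = 0.8, p_norm = 1.75),
                               list(l0 = 0.8, p0 = 1.75))$dl_norm, 0)
})

test_that("validity flags are invariant to time shifts and spatial translation", {
  course <- course_spec(c("walk", "stairs_up", "walk"), c(15, 13, 15),
                        baseline_segment = 1L)
  ses <- generate_session(course, default_effects(), participant_params(),
                          seed = 31)
  fr <- ses$frames
  base <- step_metrics(detect_steps(fr), fr)
  fr2 <- fr
  fr2$timestamp <- fr2$timestamp + 100
  for (cl in c("foot_l_x", "foot_r_x")) fr2[[cl]] <- fr2[[cl]] + 50
  for (cl in c("foot_l_z", "foot_r_z")) fr2[[cl]] <- fr2[[cl]] - 3
  shifted <- step_metrics(detect_steps(fr2), fr2)
  expect_equal(shifted$valid, base$valid)
  expect_equal(shifted$l, base$l)
  expect_equal(shifted$p, base$p)
})

test_that("step accounting conserves counts and percentages recompute", {
  ses <- generate_session(default_course(), default_effects(),
                          participant_params(), seed = 17)
  steps <- detect_steps(ses$frames)
  acc <- step_accounting(steps)
  tot <- acc[acc$mode_label == "total", ]
  expect_equal(tot$valid_steps + tot$invalid_steps, nrow(steps))
  expect_equal(acc$invalid_pct,
               round(100 * acc$invalid_steps /
                       (acc$valid_steps + acc$invalid_steps), 2))
  expect_error(invalid_percentage(-1, 5), "non-negative")
})
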