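test_that("palm vector is the thumb-tip minus wrist difference and is translation invariant", {
  set.seed(3)
  for (rep in 1:20) {
    frame <- matrix(rnorm(63), 21, 3)
    expect_equal(palm_vector(frame), frame[5, ] - frame[1, ],
                 ignore_attr = TRUE)
    shift <- matrix(rnorm(3), 21, 3, byrow = TRUE)
    expect_equal(palm_vector(frame + shift), palm_vector(frame))
  }
})

test_that("rotation angle honours the palm-forward/back-of-hand convention", {
  expect_equal(rotation_angle(make_pose(0)), 0)
  expect_equal(rotation_angle(make_pose(180)), 180)
})

test_that("rotation angle round-trips the pose generator over [0, 180]", {
  for (theta in c(10, 45, 90, 135, seq(0, 180, by = 7.5)))
    expect_equal(rotation_angle(make_pose(theta)), theta, tolerance = 1e-9)
  expect_error(make_pose(-1), "0, 180")
  expect_error(make_pose(181), "0, 180")
})

test_that("rotation angle is invariant to translation and uniform scaling", {
  set.seed(5)
  for (theta in runif(20, 0, 180)) {
    pose <- make_pose(theta)
    shift <- matrix(rnorm(3), 21, 3, byrow = TRUE)
    expect_equal(rotation_angle(pose * 3.7), theta, tolerance = 1e-9)
    expect_equal(rotation_angle(pose + shift), theta, tolerance = 1e-9)
    expect_equal(rotation_angle(pose * 0.01 + shift), theta, tolerance = 1e-9)
  }
})

test_that("degenerate frames (no horizontal palm component) yield NA and are interpolated", {
  frame <- matrix(0, 21, 3)
  frame[5, ] <- c(0, 0.2, 0)  # palm vector straight up: no x-z projection
  expect_true(is.na(rotation_angle(frame)))
  # a short degenerate gap inside a trajectory is bridged linearly
  thetas <- seq(0, 90, length.out = 10)
  coords <- t(vapply(thetas, function(th) as.vector(t(make_pose(th))),
                     numeric(63)))
  coords[5:6, ] <- 0  # tracking collapse on frames 5 and 6
  traj <- hand_trajectory(coords, fps = 30)
  s <- angle_series(traj)
  expect_equal(s$theta_deg, thetas, tolerance = 1e-9)
})

test_that("slope estimator matches the brute-force least-squares oracle", {
  set.seed(7)
  theta <- pmin(180, pmax(0, 90 + cumsum(rnorm(60, 0, 6))))
  s <- angle_series_from_theta(theta, fps = 30, window = 5)
  n <- length(theta)
  for (i in seq_len(n)) {
    w <- max(1, i - 2):min(n, i + 2)
    fit <- lm(theta[w] ~ w)
    expect_equal(s$slope_deg_per_frame[i], unname(coef(fit)[2]),
                 tolerance = 1e-9)
  }
  # constant series: slope 0 everywhere
  s0 <- angle_series_from_theta(rep(42, 30))
  expect_true(all(s0$slope_deg_per_frame == 0))
  # linear ramp 0 -> 180 over 30 frames: interior slope 180/29
  sr <- angle_series_from_theta(seq(0, 180, length.out = 30))
  expect_equal(sr$slope_deg_per_frame[3:28], rep(180 / 29, 26),
               tolerance = 1e-9)
})

test_that("phase labels follow the slope sign with deadband, ties are maintain", {
  ramp <- angle_series_from_theta(seq(0, 180, length.out = 30))
  expect_true(all(classify_phases(ramp) == "increase"))
  flat <- angle_series_from_theta(rep(90, 30))
  expect_true(all(classify_phases(flat) == "maintain"))
  # triangle wave: labels match the analytic derivative sign away from folds
  theta <- c(seq(0, 170, by = 10), seq(160, 0, by = -10))
  s <- angle_series_from_theta(theta)
  ph <- classify_phases(s)
  expect_true(all(ph[2:15] == "increase"))
  expect_true(all(ph[21:34] == "decrease"))
  # exact-deadband tie
  s2 <- angle_series_from_theta(seq(0, 29, by = 1))  # slope exactly 1
  expect_true(all(classify_phases(s2, deadband = 1) == "maintain"))
})

test_that("the ideal single full rotation over 30 frames is segmented as one 360-degree event", {
  sim <- make_trajectory(motion_profile(n_rotations_target = 1),
                         fps = 30, duration_s = 1)
  series <- angle_series(sim$trajectory)
  ev <- segment_rotations(series)
  expect_equal(nrow(ev), 1L)
  # excursion is 360 minus at most the one-frame sampling shortfall
  shortfall <- 90 * (1 - cos(2 * pi / 30))
  expect_gte(ev$excursion_deg, 360 - 2 * shortfall)
  expect_lte(ev$excursion_deg, 360)
  expect_equal(ev$duration_s, 1, tolerance = 1 / 30 + 1e-9)
  expect_equal(sign(ev$half1_deg), 1)
  expect_equal(sign(ev$half2_deg), -1)
})

test_that("segmentation matches the extremum-pairing oracle on 200 random noise-free profiles", {
  set.seed(17)
  for (rep in 1:200) {
    k <- sample(0:5, 1)
    prof <- motion_profile(
      base_amplitude_deg = runif(1, 110, 180),
      base_period_s = runif(1, 0.6, 1.5),
      n_rotations_target = k,
      period_drift_per_rotation_s = runif(1, -0.02, 0.02),
      amplitude_drift_per_rotation_deg = runif(1, -4, 4))
    sim <- make_trajectory(prof, fps = 30, duration_s = 10)
    series <- angle_series(sim$trajectory)
    ev <- segment_rotations(series)
    theta_true <- series$theta_deg  # noise-free by construction
    expect_equal(nrow(ev), oracle_count_rotations(theta_true, amp_min = 60),
                 info = sprintf("rep %d (k=%d)", rep, k))
    expect_equal(nrow(ev), nrow(sim$truth))
    # events non-overlapping and within the trial
    if (nrow(ev) > 1)
      expect_true(all(ev$start_frame[-1] >= ev$end_frame[-nrow(ev)]))
    expect_lte(sum(ev$duration_s), 10)
  }
})

test_that("sub-threshold amplitudes yield no events; motionless input yields none", {
  sim <- make_trajectory(motion_profile(base_amplitude_deg = 40,
                                        n_rotations_target = 5),
                         fps = 30, duration_s = 10)
  ev <- segment_rotations(angle_series(sim$trajectory), amp_min = 60)
  expect_equal(nrow(ev), 0L)
  flat <- angle_series_from_theta(rep(90, 300))
  expect_equal(nrow(segment_rotations(flat)), 0L)
})

test_that("a trailing unpaired half-excursion produces no event", {
  # one and a half rotations: up-down (paired) + up (incomplete)
  theta <- c(90 * (1 - cos(2 * pi * (0:29) / 30)),
             90 * (1 - cos(pi * (0:29) / 30)))
  s <- angle_series_from_theta(theta, fps = 30)
  ev <- segment_rotations(s)
  expect_equal(nrow(ev), 1L)
})

test_that("long tracking gaps split the series and no rotation spans a split", {
  theta <- 90 * (1 - cos(2 * pi * (0:119) / 30))  # 4 rotations
  theta[55:75] <- NA                              # long gap in rotation 2/3
  s <- angle_series_from_theta(theta, fps = 30)
  ev <- segment_rotations(s)
  expect_true(all(ev$end_frame <= 54 | ev$start_frame >= 75))
})
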