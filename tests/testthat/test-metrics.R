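test_that("the seven indicators match their definitions on a worked example", {
  ev <- data.frame(start_frame = c(0, 35, 65), end_frame = c(30, 62, 89),
                   duration_s = c(1.0, 0.9, 0.8),
                   excursion_deg = c(360, 350, 340))
  m <- compute_metrics(ev, trial_duration_s = 10)
  expect_equal(m$total_rotation_count, 3)
  expect_equal(m$total_rotation_time_s, 2.7)
  expect_equal(m$total_time_change_s, -0.2)
  expect_equal(m$n_time_changes, -2)
  expect_equal(m$total_rotation_angle_deg, 1050)
  expect_equal(m$total_angle_change_deg, -20)
  expect_equal(m$n_angle_changes, -2)
})

test_that("no events yields all-zero indicators", {
  m <- compute_metrics(random_events(0))
  expect_true(all(unlist(m) == 0))
})

test_that("indicators equal a brute-force per-definition loop on 300 random event lists", {
  set.seed(23)
  for (rep in 1:300) {
    ev <- random_events(sample(0:12, 1))
    m <- compute_metrics(ev, trial_duration_s = 20)
    n <- nrow(ev)
    tca <- 0; ntc <- 0; aca <- 0; nac <- 0
    if (n >= 2) for (i in 2:n) {
      tca <- tca + (ev$duration_s[i] - ev$duration_s[i - 1])
      ntc <- ntc + sign(ev$duration_s[i] - ev$duration_s[i - 1])
      aca <- aca + (ev$excursion_deg[i] - ev$excursion_deg[i - 1])
      nac <- nac + sign(ev$excursion_deg[i] - ev$excursion_deg[i - 1])
    }
    expect_equal(m$total_rotation_count, n)
    expect_equal(m$total_rotation_time_s, sum(ev$duration_s))
    expect_equal(m$total_time_change_s, tca)
    expect_equal(m$n_time_changes, ntc)
    expect_equal(m$total_rotation_angle_deg, sum(ev$excursion_deg))
    expect_equal(m$total_angle_change_deg, aca)
    expect_equal(m$n_angle_changes, nac)
    # telescoping identities
    if (n >= 2) {
      expect_equal(m$total_time_change_s,
                   ev$duration_s[n] - ev$duration_s[1])
      expect_equal(m$total_angle_change_deg,
                   ev$excursion_deg[n] - ev$excursion_deg[1])
      expect_lte(abs(m$n_time_changes), n - 1)
      expect_lte(abs(m$n_angle_changes), n - 1)
    }
  }
})

test_that("ties contribute zero to the signed tallies", {
  ev <- random_events(3)
  ev$duration_s <- rep(0.8, 3)
  ev$excursion_deg <- rep(300, 3)
  m <- compute_metrics(ev, 10)
  expect_equal(m$n_time_changes, 0)
  expect_equal(m$n_angle_changes, 0)
})

test_that("overlapping or out-of-window events are integrity errors", {
  ev <- random_events(3)
  bad <- ev; bad$start_frame[2] <- bad$end_frame[1] - 2
  expect_error(compute_metrics(bad, 10), "overlap")
  bad <- ev; bad$duration_s <- rep(5, 3)
  expect_error(compute_metrics(bad, 10), "trial window")
})

test_that("speeding-up and amplitude-decay generators drive the signed indicators negative", {
  sim <- make_trajectory(
    motion_profile(base_period_s = 1.2, n_rotations_target = 6,
                   period_drift_per_rotation_s = -0.06),
    fps = 30, duration_s = 10)
  m <- compute_metrics(segment_rotations(angle_series(sim$trajectory)), 10)
  expect_lt(m$total_time_change_s, 0)
  expect_lt(m$n_time_changes, 0)
  sim2 <- make_trajectory(
    motion_profile(base_amplitude_deg = 180, n_rotations_target = 6,
                   amplitude_drift_per_rotation_deg = -12),
    fps = 30, duration_s = 10)
  m2 <- compute_metrics(segment_rotations(angle_series(sim2$trajectory)), 10)
  expect_lt(m2$total_angle_change_deg, 0)
  expect_lt(m2$n_angle_changes, 0)
})

test_that("the metric pipeline recovers programmed ground truth over seeded profiles", {
  set.seed(31)
  for (rep in 1:100) {
    noisy <- rep > 50
    prof <- motion_profile(
      base_amplitude_deg = runif(1, 120, 180),
      base_period_s = runif(1, 0.8, 1.6),
      n_rotations_target = sample(1:5, 1),
      angle_noise_sd_deg = if (noisy) runif(1, 0.5, 1.5) else 0,
      seed = 1000 + rep)
    sim <- make_trajectory(prof, fps = 30, duration_s = 10)
    ev <- segment_rotations(angle_series(sim$trajectory))
    m <- compute_metrics(ev, 10)
    # count recovered exactly, with or without noise
    expect_equal(m$total_rotation_count, nrow(sim$truth))
    if (!noisy) {
      # noise-free: each boundary anchor lands within one frame of truth
      expect_lte(max(abs(ev$duration_s - sim$truth$duration_s)),
                 2 / 30 + 1e-9)
      expect_lt(max(abs(ev$excursion_deg - sim$truth$excursion_deg)), 10)
    } else {
      # angle noise lets anchors wander on the flat reversals; boundary
      # anchors are confined to the slope-window margin around motion edges
      expect_lte(max(abs(ev$duration_s - sim$truth$duration_s)),
                 7 / 30 + 1e-9)
      expect_lt(max(abs(ev$excursion_deg - sim$truth$excursion_deg)), 25)
    }
  }
})

test_that("metrics_table assembles the long cohort table and reports missing cells", {
  roster <- tiny_roster()
  recs <- list()
  for (pid in roster$participant_id) for (hand in c("left", "right"))
    for (trial in 1:3) {
      if (pid == "O01" && hand == "left" && trial == 2) next  # missing cell
      sim <- make_trajectory(motion_profile(n_rotations_target = 3,
                                            seed = trial),
                             fps = 30, duration_s = 10, hand = hand)
      recs[[length(recs) + 1]] <- trial_recording(pid, hand, trial,
                                                  sim$trajectory)
    }
  tab <- metrics_table(recs, roster)
  expect_equal(nrow(tab), 11)
  miss <- attr(tab, "missing")
  expect_equal(nrow(miss), 1)
  expect_equal(miss$participant_id, "O01")
  expect_equal(miss$trial, 2)
  # batch rows equal the single-recording path
  one <- recs[[1]]
  m1 <- compute_metrics(segment_rotations(angle_series(one$trajectory)), 10)
  row <- tab[tab$participant_id == one$participant_id &
             tab$hand == one$hand & tab$trial == one$trial, ]
  expect_equal(unlist(row[names(m1)]), unlist(m1), ignore_attr = TRUE)
})
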