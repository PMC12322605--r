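test_that("marginal estimates equal the OLS oracle on balanced Gaussian data", {
  for (seed in c(1, 2, 3)) {
    d <- simulate_cohort(cohort_spec(seed = seed))
    f <- fit_marginal_model(d, "total_rotation_count")
    ols <- lm(total_rotation_count ~ factor(group, c("older", "young")) +
                factor(hand, c("right", "left")) + factor(trial), data = d)
    expect_equal(f$coefficients$B, unname(coef(ols)), tolerance = 1e-9)
    # same exactness with interactions
    fi <- fit_marginal_model(d, "total_rotation_count",
                             include_interactions = TRUE)
    oi <- lm(total_rotation_count ~ g + h + t + g:h + g:t,
             data = data.frame(total_rotation_count = d$total_rotation_count,
                               g = factor(d$group, c("older", "young")),
                               h = factor(d$hand, c("right", "left")),
                               t = factor(d$trial)))
    expect_equal(sort(fi$coefficients$B), sort(unname(coef(oi))),
                 tolerance = 1e-9)
  }
})

test_that("the group coefficient is positive when young outperform older", {
  d <- simulate_cohort(cohort_spec(seed = 44))
  for (m in c("total_rotation_count", "total_rotation_angle_deg")) {
    f <- fit_marginal_model(d, m)
    expect_gt(f$coefficients$B[f$coefficients$term == "groupyoung"], 0)
  }
})

test_that("a programmed +5 group effect on count is recovered with small bias", {
  mp <- handrot:::.default_metric_params()
  mp$mean_young <- mp$mean_older
  mp$sd_young <- mp$sd_older
  mp$trial2 <- 0; mp$trial3 <- 0; mp$hand_left <- 0
  mp$mean_young[mp$metric == "total_rotation_count"] <-
    mp$mean_older[mp$metric == "total_rotation_count"] + 5
  set.seed(200)
  seeds <- sample.int(2^31 - 2, 200)
  est <- vapply(seeds, function(s) {
    d <- simulate_cohort(cohort_spec(metric_params = mp, seed = s))
    f <- fit_marginal_model(d, "total_rotation_count")
    f$coefficients$B[f$coefficients$term == "groupyoung"]
  }, numeric(1))
  expect_lt(abs(mean(est) - 5), 0.5)
  expect_lt(abs(mean(est) - 5) / 5, 0.10)  # bias under 10%
})

test_that("estimated working correlation tracks the programmed rho", {
  d <- simulate_cohort(cohort_spec(n_young = 200, n_older = 200, rho = 0.5,
                                   null = TRUE, seed = 31))
  f <- fit_marginal_model(d, "total_rotation_angle_deg")
  expect_equal(f$alpha, 0.5, tolerance = 0.08)
})

test_that("coefficient table is internally consistent (z = B/SE, SE > 0)", {
  d <- simulate_cohort(cohort_spec(seed = 9))
  f <- fit_marginal_model(d, "total_rotation_time_s")
  expect_true(all(f$coefficients$SE > 0))
  expect_equal(f$coefficients$z, f$coefficients$B / f$coefficients$SE)
  expect_equal(f$coefficients$p,
               2 * pnorm(-abs(f$coefficients$z)))
})

test_that("degenerate designs raise model-spec errors", {
  d <- simulate_cohort(cohort_spec(seed = 10))
  expect_error(fit_marginal_model(d[d$trial == 1, ], "total_rotation_count"),
               "rank deficient")
  expect_error(fit_marginal_model(d[d$group == "young", ],
                                  "total_rotation_count"), "both age groups")
  expect_error(fit_marginal_model(d, "not_a_metric"), "schema error")
})

test_that("paired post-hoc t-tests match the closed-form oracle", {
  d <- simulate_cohort(cohort_spec(seed = 55))
  ph <- posthoc_trials(d, "total_rotation_count")
  agg <- aggregate(total_rotation_count ~ participant_id + trial, d, mean)
  for (i in seq_len(nrow(ph))) {
    xi <- agg$total_rotation_count[agg$trial == ph$trial_i[i]]
    xj <- agg$total_rotation_count[agg$trial == ph$trial_j[i]]
    dd <- xi - xj
    t_oracle <- mean(dd) / (sd(dd) / sqrt(length(dd)))
    p_oracle <- 2 * pt(-abs(t_oracle), length(dd) - 1)
    expect_equal(ph$t[i], t_oracle, tolerance = 1e-9)
    expect_equal(ph$df[i], length(dd) - 1)
    expect_equal(ph$p[i], p_oracle, tolerance = 1e-9)
    expect_equal(ph$p_bonferroni[i], min(1, 3 * p_oracle), tolerance = 1e-9)
  }
  expect_equal(ph$n, rep(68, 3))
})

test_that("Bonferroni adjustment is monotone in raw p and capped at one", {
  d <- simulate_cohort(cohort_spec(seed = 56))
  ph <- posthoc_trials(d, "total_rotation_angle_deg")
  expect_true(all(ph$p_bonferroni >= ph$p))
  expect_true(all(ph$p_bonferroni <= 1))
  expect_equal(order(ph$p), order(ph$p_bonferroni))
  # the printed worked example: raw p of 0.000007 adjusts to 0.000021
  expect_equal(min(1, 3 * 0.000007), 0.000021)
})

test_that("identical trial means give t = 0 and adjusted p = 1", {
  d <- simulate_cohort(cohort_spec(seed = 57))
  d$flat <- rep(as.numeric(factor(d$participant_id)), 1)  # constant per id
  ph <- posthoc_trials(d, "flat")
  expect_true(all(abs(ph$t) < 1e-12))
  expect_true(all(ph$p_bonferroni == 1))
})

test_that("Hedges g uses the pooled-SD form with small-sample correction", {
  x <- c(10, 12, 14, 16, 18)
  y <- c(11, 14, 15, 18, 21)
  n <- 5
  sp <- sqrt((var(x) + var(y)) / 2)
  J <- 1 - 3 / (4 * (2 * n - 2) - 1)
  expect_equal(hedges_g(x, y), (mean(x) - mean(y)) / sp * J)
  expect_equal(hedges_g(x, x), 0)
  expect_error(hedges_g(rep(1, 5), rep(1, 5)), "zero pooled SD")
  expect_error(hedges_g(x, y[1:3]), "paired")
  # improvement on the later condition yields negative g in (earlier, later)
  expect_lt(hedges_g(x, x + 2), 0)
})

test_that("participants missing a trial are dropped from post hoc and logged", {
  d <- simulate_cohort(cohort_spec(seed = 58))
  d <- d[!(d$participant_id == "P001" & d$trial == 3), ]
  ph <- posthoc_trials(d, "total_rotation_count")
  expect_equal(ph$n, rep(67, 3))
  expect_equal(attr(ph, "dropped"), "P001")
})

test_that("the analysis report flags programmed effects and the learning plateau", {
  d <- simulate_cohort(cohort_spec(seed = 60))
  rep_ <- analysis_report(d)
  expect_s3_class(rep_, "hr_report")
  cnt <- rep_$metrics$total_rotation_count
  expect_lt(cnt$p_group, 0.05)
  expect_true(cnt$trial_significant)
  expect_false(is.null(cnt$posthoc))
  # JSON serialization round-trips to identical rendered content
  f <- withr::local_tempfile(fileext = ".json")
  report_json(rep_, f)
  expect_identical(jsonlite::fromJSON(f, simplifyVector = FALSE),
                   jsonlite::fromJSON(as.character(report_json(rep_)),
                                      simplifyVector = FALSE))
})

test_that("an all-null cohort rarely flags the group effect", {
  set.seed(61)
  flags <- replicate(20, {
    d <- simulate_cohort(cohort_spec(null = TRUE))
    r <- analysis_report(d)
    r$metrics$total_rotation_count$p_group < 0.05
  })
  expect_lte(sum(flags), 4)  # ~1 expected at the nominal level
})
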