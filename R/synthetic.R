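# Synthetic data: a canonical hand-landmark template, single-trial rotation
# trajectories with programmed ground truth, synthetic rosters, and
# metric-level cohort simulation with the mixed (group x hand x trial)
# structure the statistical stage assumes.

#' Canonical palm-forward hand template
#'
#' A stylized 21-landmark right hand (standard landmark topology: wrist 0;
#' thumb 1-4; index 5-8; middle 9-12; ring 13-16; pinky 17-20) facing the
#' camera (palm toward +z), fingers up (+y), in normalized image-like units.
#' The wrist sits at the origin so rotations about the vertical axis pivot
#' about the forearm.
#'
#' @return 21 x 3 matrix (columns x, y, z).
#' @export
hand_template <- function() {
  m <- matrix(c(
     0.000, 0.000, 0.000,   # 0 wrist
     0.040, 0.030, 0.015,   # 1 thumb cmc
     0.080, 0.060, 0.025,   # 2 thumb mcp
     0.110, 0.085, 0.030,   # 3 thumb ip
     0.130, 0.105, 0.030,   # 4 thumb tip
     0.045, 0.130, 0.005,   # 5 index mcp
     0.050, 0.175, 0.008,   # 6 index pip
     0.053, 0.205, 0.010,   # 7 index dip
     0.055, 0.230, 0.010,   # 8 index tip
     0.015, 0.135, 0.000,   # 9 middle mcp
     0.017, 0.185, 0.004,   # 10 middle pip
     0.018, 0.220, 0.006,   # 11 middle dip
     0.019, 0.245, 0.006,   # 12 middle tip
    -0.015, 0.130, 0.000,   # 13 ring mcp
    -0.018, 0.175, 0.004,   # 14 ring pip
    -0.020, 0.205, 0.006,   # 15 ring dip
    -0.021, 0.228, 0.006,   # 16 ring tip
    -0.045, 0.120, 0.002,   # 17 pinky mcp
    -0.050, 0.155, 0.005,   # 18 pinky pip
    -0.053, 0.180, 0.006,   # 19 pinky dip
    -0.055, 0.200, 0.006),  # 20 pinky tip
    ncol = 3, byrow = TRUE, dimnames = list(NULL, c("x", "y", "z")))
  m
}

#' Render a hand pose at a given rotation angle
#'
#' Rotates the palm-forward template by `theta` degrees about the vertical
#' (y) axis through the wrist, so that
#' `rotation_angle(make_pose(theta)) == theta`.
#'
#' @param theta rotation angle in degrees, in `[0, 180]`.
#' @param template landmark template (default [hand_template()]).
#' @return 21 x 3 landmark matrix.
#' @export
make_pose <- function(theta, template = hand_template()) {
  if (!is.numeric(theta) || length(theta) != 1L || is.na(theta) ||
      theta < 0 || theta > 180)
    stop("theta must be a single angle in [0, 180] degrees")
  rad <- theta * pi / 180
  co <- cos(rad); si <- sin(rad)
  x <- template[, 1]; z <- template[, 3]
  out <- template
  out[, 1] <- co * x + si * z
  out[, 3] <- -si * x + co * z
  out
}

#' Motion profile for a synthetic rotation trial
#'
#' Describes a sequence of full rotations (each a 0 -> amplitude -> 0 degree
#' excursion traced as a raised-cosine half-cycle in each direction): the
#' smooth near-zero-slope reversals exercise the deadband/"maintain" logic
#' the segmenter must handle. Per-rotation drift emulates speeding up /
#' slowing down and amplitude growth/decay across the trial.
#'
#' @param base_amplitude_deg half-excursion amplitude of the first rotation,
#'   in `(0, 180]` (nominal 180).
#' @param base_period_s duration of the first full rotation (nominal 1 s:
#'   ~30 frames at 30 fps).
#' @param n_rotations_target number of full rotations to program.
#' @param period_drift_per_rotation_s signed per-rotation change in period.
#' @param amplitude_drift_per_rotation_deg signed per-rotation change in
#'   amplitude; drift driving amplitude to 0 stops generation early.
#' @param angle_noise_sd_deg Gaussian noise SD added to theta per frame.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @export
motion_profile <- function(base_amplitude_deg = 180, base_period_s = 1,
                           n_rotations_target = 8L,
                           period_drift_per_rotation_s = 0,
                           amplitude_drift_per_rotation_deg = 0,
                           angle_noise_sd_deg = 0, seed = NULL) {
  if (base_amplitude_deg <= 0 || base_amplitude_deg > 180)
    stop("base_amplitude_deg must be in (0, 180]")
  if (base_period_s <= 0) stop("base_period_s must be positive")
  if (angle_noise_sd_deg < 0) stop("angle_noise_sd_deg must be >= 0")
  structure(list(base_amplitude_deg = base_amplitude_deg,
                 base_period_s = base_period_s,
                 n_rotations_target = as.integer(n_rotations_target),
                 period_drift_per_rotation_s = period_drift_per_rotation_s,
                 amplitude_drift_per_rotation_deg =
                   amplitude_drift_per_rotation_deg,
                 angle_noise_sd_deg = angle_noise_sd_deg,
                 seed = seed),
            class = "motion_profile")
}

#' Generate a synthetic rotation trajectory with ground truth
#'
#' Builds the continuous rotation-angle signal programmed by `profile`,
#' samples it on the frame grid `t = k / fps` (a video of n frames spans
#' n / fps seconds), adds optional Gaussian angle noise (clamped to
#' `[0, 180]`), and renders every frame through [make_pose()].
#'
#' @param profile a [motion_profile()].
#' @param fps frames per second (default 30).
#' @param duration_s trial length in seconds (default 10).
#' @param hand hand label for the trajectory.
#' @return List with `trajectory` (a [hand_trajectory()]) and `truth`, a data
#'   frame of the programmed rotations that fit inside the trial window:
#'   `start_s`, `end_s`, `start_frame`, `end_frame`, `duration_s`,
#'   `amplitude_deg` (half-excursion) and `excursion_deg` (nominal total,
#'   twice the amplitude). Attribute `truncated` flags early stop from
#'   amplitude drift reaching zero.
#' @export
make_trajectory <- function(profile, fps = 30, duration_s = 10,
                            hand = "right") {
  stopifnot(inherits(profile, "motion_profile"))
  if (!is.null(profile$seed)) set.seed(profile$seed)
  k <- profile$n_rotations_target
  periods <- profile$base_period_s +
    (seq_len(k) - 1) * profile$period_drift_per_rotation_s
  amps <- profile$base_amplitude_deg +
    (seq_len(k) - 1) * profile$amplitude_drift_per_rotation_deg
  keep <- periods > 0 & amps > 0
  truncated <- FALSE
  if (!all(keep)) {
    first_bad <- which(!keep)[1]
    periods <- periods[seq_len(first_bad - 1L)]
    amps <- amps[seq_len(first_bad - 1L)]
    truncated <- TRUE
  }
  starts <- cumsum(c(0, periods))[seq_along(periods)]
  ends <- starts + periods
  n <- round(fps * duration_s)
  t <- (seq_len(n) - 1) / fps
  theta <- numeric(n)
  for (i in seq_along(periods)) {
    in_rot <- t >= starts[i] & t < ends[i]
    if (any(in_rot)) {
      s <- t[in_rot] - starts[i]
      theta[in_rot] <- amps[i] / 2 * (1 - cos(2 * pi * s / periods[i]))
    }
  }
  if (profile$angle_noise_sd_deg > 0)
    theta <- pmin(180, pmax(0, theta +
      stats::rnorm(n, 0, profile$angle_noise_sd_deg)))
  tmpl <- hand_template()
  rad <- theta * pi / 180
  co <- cos(rad); si <- sin(rad)
  coords <- matrix(0, n, 3L * N_LANDMARKS)
  for (lm in seq_len(N_LANDMARKS)) {
    x <- tmpl[lm, 1]; y <- tmpl[lm, 2]; z <- tmpl[lm, 3]
    coords[, 3L * lm - 2L] <- co * x + si * z
    coords[, 3L * lm - 1L] <- y
    coords[, 3L * lm] <- -si * x + co * z
  }
  complete <- ends <= duration_s + 1e-9
  truth <- data.frame(start_s = starts[complete], end_s = ends[complete],
                      start_frame = pmin(n - 1L, round(starts[complete] * fps)),
                      end_frame = pmin(n - 1L, round(ends[complete] * fps)),
                      duration_s = periods[complete],
                      amplitude_deg = amps[complete],
                      excursion_deg = 2 * amps[complete])
  attr(truth, "truncated") <- truncated
  list(trajectory = hand_trajectory(coords, fps = fps, hand = hand,
                                    duration_s = duration_s),
       truth = truth)
}

# ---- cohort simulation -----------------------------------------------------

# Default per-metric cohort parameters: group means/SDs from the reference
# study population (young n=29, older n=39), additive trial-2/3 learning
# shifts for the metrics where a trial effect was reported, no hand effect.
.default_metric_params <- function() {
  data.frame(
    metric = METRIC_NAMES,
    mean_young = c(25.66, 8.77, -0.00, 0.11, 4679.74, -1.65, 0.19),
    sd_young   = c(7.16, 1.53, 0.09, 2.09, 3209.04, 45.16, 3.46),
    mean_older = c(19.56, 7.37, -0.03, -0.18, 2718.68, -2.98, -0.62),
    sd_older   = c(7.02, 1.84, 0.14, 1.83, 1235.20, 33.22, 3.17),
    trial2 = c(1.77, 0.33, 0, 0, 193.69, 0, 0),
    trial3 = c(2.31, 0.32, 0, 0, 295.09, 0, 0),
    hand_left = c(0, 0, 0, 0, 0, 0, 0))
}

#' Cohort simulation specification
#'
#' Metric-level generative model for a mixed-design cohort: for participant
#' `i` in group `g`, cell (hand, trial) of metric `m` is
#' `mean_g[m] + trial_effect[m] + hand_effect[m] + u_im + e`, with
#' `u_im ~ N(0, rho * sd_g[m]^2)` a participant random effect and
#' `e ~ N(0, (1 - rho) * sd_g[m]^2)`, inducing exchangeable correlation
#' `rho` across each participant's six cells.
#'
#' @param n_young,n_older group sizes (defaults 29 / 39).
#' @param metric_params data frame with columns `metric`, `mean_young`,
#'   `sd_young`, `mean_older`, `sd_older`, `trial2`, `trial3`, `hand_left`;
#'   defaults to the reference-population values.
#' @param rho within-participant exchangeable correlation in `[0, 1)`.
#' @param null if `TRUE`, zero out all group, trial and hand effects (older
#'   means and SDs for both groups): the null configuration used for type-I
#'   error calibration.
#' @param seed integer seed (used by [simulate_cohort()]).
#' @export
cohort_spec <- function(n_young = 29L, n_older = 39L,
                        metric_params = .default_metric_params(),
                        rho = 0.5, null = FALSE, seed = NULL) {
  if (rho < 0 || rho >= 1) stop("config error: rho must be in [0, 1)")
  if (n_young < 1L || n_older < 1L) stop("config error: empty group")
  need <- c("metric", "mean_young", "sd_young", "mean_older", "sd_older",
            "trial2", "trial3", "hand_left")
  if (!all(need %in% names(metric_params)))
    stop("config error: metric_params missing columns")
  if (any(metric_params$sd_young <= 0) || any(metric_params$sd_older <= 0))
    stop("config error: SDs must be positive")
  if (null) {
    metric_params$mean_young <- metric_params$mean_older
    metric_params$sd_young <- metric_params$sd_older
    metric_params$trial2 <- 0
    metric_params$trial3 <- 0
    metric_params$hand_left <- 0
  }
  structure(list(n_young = as.integer(n_young),
                 n_older = as.integer(n_older),
                 metric_params = metric_params, rho = rho, seed = seed),
            class = "cohort_spec")
}

#' Simulate a metric-level cohort dataset
#'
#' Draws the long-format analysis table (participants x 2 hands x 3 trials)
#' under the generative model of [cohort_spec()]. Consistency coercion:
#' rotation counts are rounded and floored at 0; total rotation time is
#' clipped to the trial window `[0, 10]` s. Other indicators are left
#' continuous.
#'
#' @param spec a [cohort_spec()].
#' @return Data frame with columns `participant_id`, `group`, `hand`,
#'   `trial` and the seven metric columns; attribute `spec` records the
#'   generating specification.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  mp <- spec$metric_params
  n_total <- spec$n_young + spec$n_older
  ids <- sprintf("P%03d", seq_len(n_total))
  groups <- c(rep("young", spec$n_young), rep("older", spec$n_older))
  grid <- expand.grid(hand = c("left", "right"), trial = 1:3,
                      stringsAsFactors = FALSE)   # 6 cells, fixed order
  out <- data.frame(
    participant_id = rep(ids, each = 6L),
    group = rep(groups, each = 6L),
    hand = rep(grid$hand, n_total),
    trial = rep(grid$trial, n_total))
  rho <- spec$rho
  for (r in seq_len(nrow(mp))) {
    mu <- ifelse(out$group == "young", mp$mean_young[r], mp$mean_older[r])
    sdv <- ifelse(out$group == "young", mp$sd_young[r], mp$sd_older[r])
    mu <- mu + ifelse(out$trial == 2, mp$trial2[r],
                      ifelse(out$trial == 3, mp$trial3[r], 0)) +
      ifelse(out$hand == "left", mp$hand_left[r], 0)
    u <- rep(stats::rnorm(n_total, 0, sqrt(rho)), each = 6L) * sdv
    e <- stats::rnorm(nrow(out), 0, sqrt(1 - rho)) * sdv
    val <- mu + u + e
    if (mp$metric[r] == "total_rotation_count") val <- pmax(0, round(val))
    if (mp$metric[r] == "total_rotation_time_s") val <- pmin(10, pmax(0, val))
    out[[mp$metric[r]]] <- val
  }
  structure(out, spec = spec)
}

#' Generate a synthetic participant roster
#'
#' Ages uniform within each group's range; gender, dominant hand and
#' education sampled with the reference study's approximate proportions;
#' three Purdue Pegboard scores drawn from the age/gender norm cell
#' (rounded, floored at 0).
#'
#' @param n_young,n_older group sizes.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return Roster data frame accepted by [validate_roster()].
#' @export
make_roster <- function(n_young = 29L, n_older = 39L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- n_young + n_older
  group <- c(rep("young", n_young), rep("older", n_older))
  age <- ifelse(group == "young", sample(20:29, n, replace = TRUE),
                sample(65:80, n, replace = TRUE))
  p_male <- ifelse(group == "young", 17 / 29, 5 / 39)
  gender <- ifelse(stats::runif(n) < p_male, "male", "female")
  p_left <- ifelse(group == "young", 6 / 29, 1 / 39)
  dominant_hand <- ifelse(stats::runif(n) < p_left, "left", "right")
  education <- ifelse(group == "young",
                      sample(c("high_school", "college_plus"), n,
                             replace = TRUE, prob = c(0.9, 0.1)),
                      sample(c("none", "elementary", "middle_school",
                               "high_school", "college_plus"), n,
                             replace = TRUE,
                             prob = c(0.08, 0.18, 0.33, 0.26, 0.15)))
  norms <- ppt_norms()
  band <- ifelse(group == "young", "20-29", "60+")
  idx <- match(paste(band, gender), paste(norms$age_band, norms$gender))
  ppt <- vapply(seq_len(n), function(i)
    pmax(0, round(stats::rnorm(3, norms$mean[idx[i]], norms$sd[idx[i]]))),
    numeric(3))
  data.frame(participant_id = sprintf("P%03d", seq_len(n)), group = group,
             age = age, gender = gender, dominant_hand = dominant_hand,
             education = education,
             ppt_1 = ppt[1, ], ppt_2 = ppt[2, ], ppt_3 = ppt[3, ])
}
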