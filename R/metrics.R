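# The seven per-trial indicators, computed from segmented rotation events.
#
# With per-rotation durations t_1..t_n (s) and excursions a_1..a_n (deg):
#   total_rotation_count      n
#   total_rotation_time_s     sum t_i
#   total_time_change_s       sum_{i>=2} (t_i - t_{i-1})  (TCA; telescopes to
#                             t_n - t_1; negative = speeding up)
#   n_time_changes            sum_{i>=2} sign(t_i - t_{i-1})  (signed tally)
#   total_rotation_angle_deg  sum a_i
#   total_angle_change_deg    sum_{i>=2} (a_i - a_{i-1})  (ACA; a_n - a_1;
#                             negative = shrinking amplitude)
#   n_angle_changes           sum_{i>=2} sign(a_i - a_{i-1})
# The change tallies are signed (+1 increase / -1 decrease / 0 tie per
# consecutive pair): cohort means of these indicators are near zero and can
# be negative, which an unsigned count could not produce.

#' Names of the seven per-trial rotation indicators
#' @export
METRIC_NAMES <- c("total_rotation_count", "total_rotation_time_s",
                  "total_time_change_s", "n_time_changes",
                  "total_rotation_angle_deg", "total_angle_change_deg",
                  "n_angle_changes")

#' Compute the seven rotation indicators for one trial
#'
#' @param events rotation events from [segment_rotations()] (columns
#'   `start_frame`, `end_frame`, `duration_s`, `excursion_deg`), time-ordered.
#'   Incomplete trailing half-rotations never reach this point: every event
#'   is one full rotation.
#' @param trial_duration_s trial length in seconds (default 10).
#' @return One-row data frame with the seven indicator columns.
#' @export
compute_metrics <- function(events, trial_duration_s = 10) {
  events <- as.data.frame(events)
  n <- nrow(events)
  if (n > 0) {
    if (is.unsorted(events$start_frame, strictly = TRUE))
      stop("integrity error: events not strictly time-ordered")
    if (n > 1 && any(events$start_frame[-1] < events$end_frame[-n]))
      stop("integrity error: overlapping rotation events")
    if (any(events$duration_s < 0) ||
        sum(events$duration_s) > trial_duration_s + 1e-9)
      stop("integrity error: event durations exceed the trial window")
  }
  t <- events$duration_s
  a <- events$excursion_deg
  dt <- if (n >= 2) diff(t) else numeric(0)
  da <- if (n >= 2) diff(a) else numeric(0)
  data.frame(
    total_rotation_count = n,
    total_rotation_time_s = sum(t),
    total_time_change_s = sum(dt),
    n_time_changes = sum(sign(dt)),
    total_rotation_angle_deg = sum(a),
    total_angle_change_deg = sum(da),
    n_angle_changes = sum(sign(da)))
}

#' Build the long-format cohort metrics table
#'
#' Runs the kinematic pipeline (angle series, segmentation, indicators) on
#' every trial recording and assembles the analysis dataset: one row per
#' (participant, hand, trial) with the seven indicators and the participant's
#' group label. Cells absent from `recordings` are reported in the
#' `"missing"` attribute, never imputed.
#'
#' @param recordings list of [trial_recording()] objects.
#' @param roster validated roster supplying each participant's group.
#' @param window,deadband,amp_min,max_gap kinematics parameters passed to
#'   [angle_series()] and [segment_rotations()].
#' @return Data frame with columns `participant_id`, `group`, `hand`,
#'   `trial`, then the seven metric columns; attribute `missing` lists
#'   expected cells without a recording.
#' @export
metrics_table <- function(recordings, roster, window = 5L, deadband = 1,
                          amp_min = 60, max_gap = 5L) {
  roster <- validate_roster(roster)
  keys <- vapply(recordings, function(r)
    paste(r$participant_id, r$hand, r$trial, sep = "|"), character(1))
  if (anyDuplicated(keys))
    stop("duplicate (participant, hand, trial) recordings: ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  rows <- lapply(recordings, function(rec) {
    grp <- roster$group[match(rec$participant_id, roster$participant_id)]
    if (is.na(grp))
      stop("recording for unknown participant: ", rec$participant_id)
    series <- angle_series(rec$trajectory, window = window, max_gap = max_gap)
    ev <- segment_rotations(series, amp_min = amp_min, deadband = deadband)
    cbind(data.frame(participant_id = rec$participant_id, group = grp,
                     hand = rec$hand, trial = rec$trial),
          compute_metrics(ev, trial_duration_s = rec$trajectory$duration_s))
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    cbind(data.frame(participant_id = character(0), group = character(0),
                     hand = character(0), trial = integer(0)),
          compute_metrics(data.frame())[0, ])
  grid <- expand.grid(participant_id = roster$participant_id,
                      hand = c("left", "right"), trial = 1:3,
                      stringsAsFactors = FALSE)
  gk <- paste(grid$participant_id, grid$hand, grid$trial, sep = "|")
  miss <- grid[!gk %in% keys, , drop = FALSE]
  rownames(miss) <- NULL
  rownames(out) <- NULL
  structure(out, missing = miss)
}
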