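# Rotation-angle signal and full-rotation segmentation.
#
# The palm orientation of one frame is summarized by the wrist -> thumb-tip
# position vector (landmarks 0 and 4). The rotation angle theta in [0, 180]
# degrees is the angle of the shortest-arc quaternion, about the camera-frame
# vertical (y) axis, that maps the canonical palm-forward reference vector
# onto the observed palm vector's projection into the horizontal x-z plane:
# 0 deg = palm facing the camera, 180 deg = back of hand facing the camera.
# Pronation/supination rotates the hand about the (upright) forearm, so only
# the horizontal components carry the rotation; projecting makes theta
# invariant to translation, uniform scaling, and vertical wobble.

LM_WRIST <- 1L      # landmark 0
LM_THUMB_TIP <- 5L  # landmark 4

#' Wrist-to-thumb-tip palm vector
#'
#' @param frame a 21 x 3 landmark matrix (see [landmark_frame()]).
#' @return Numeric length-3 vector `points[4] - points[0]` (unnormalized).
#'   A zero-length vector (coincident landmarks) is returned as-is; angle
#'   computation flags it as degenerate.
#' @export
palm_vector <- function(frame) {
  frame <- as.matrix(frame)
  stopifnot(nrow(frame) == N_LANDMARKS, ncol(frame) == 3L)
  unname(frame[LM_THUMB_TIP, ] - frame[LM_WRIST, ])
}

# Reference direction: the x-z projection of the canonical palm-forward
# template's palm vector, unit length. Computed once per session.
.palm_ref <- local({
  ref <- NULL
  function() {
    if (is.null(ref)) {
      v <- palm_vector(hand_template())
      p <- c(v[1], v[3])
      ref <<- p / sqrt(sum(p^2))
    }
    ref
  }
})

.DEGENERATE_EPS <- 1e-9

# Vectorized core: vx, vz are horizontal palm-vector components per frame.
# Returns theta in [0, 180] with NA for degenerate frames.
.theta_from_xz <- function(vx, vz) {
  r <- .palm_ref()
  nrm <- sqrt(vx^2 + vz^2)
  dot <- vx * r[1] + vz * r[2]
  crs <- vx * r[2] - vz * r[1]
  # angle of the shortest-arc quaternion about y mapping the reference onto
  # the observed horizontal direction; atan2 keeps full precision at the
  # 0 and 180 degree endpoints where acos degrades
  theta <- atan2(abs(crs), dot) * 180 / pi
  theta[nrm < .DEGENERATE_EPS] <- NA_real_
  theta
}

#' Rotation angle of one frame
#'
#' @param frame a 21 x 3 landmark matrix.
#' @return Angle in degrees in `[0, 180]`; `NA` for a degenerate frame whose
#'   palm vector has no horizontal component (tracking collapse).
#' @export
rotation_angle <- function(frame) {
  v <- palm_vector(frame)
  .theta_from_xz(v[1], v[3])
}

#' Per-frame rotation angles and 5-frame slopes for a trajectory
#'
#' Computes theta for every frame, linearly interpolates theta across short
#' degenerate gaps (at most `max_gap` frames; longer gaps stay `NA` and split
#' the series for segmentation), and estimates the per-frame slope as the
#' ordinary least-squares slope of theta over a centered `window`-frame
#' window, truncated at the edges (at least 2 usable frames, else `NA`).
#'
#' @param traj a [hand_trajectory()].
#' @param window slope window in frames (default 5).
#' @param max_gap longest degenerate gap (frames) bridged by interpolation.
#' @return An `angle_series`: data frame with columns `frame`, `time_s`,
#'   `theta_deg`, `slope_deg_per_frame`, with the fps kept as an attribute.
#' @export
angle_series <- function(traj, window = 5L, max_gap = 5L) {
  stopifnot(inherits(traj, "hand_trajectory"))
  n <- n_frames(traj)
  if (n < window)
    stop("short-series error: ", n, " frames but slope window is ", window)
  vx <- traj$coords[, "x4"] - traj$coords[, "x0"]
  vz <- traj$coords[, "z4"] - traj$coords[, "z0"]
  theta <- .theta_from_xz(vx, vz)
  theta <- .bridge_gaps(theta, max_gap)
  .build_angle_series(theta, fps = traj$fps, time_s = traj$time_s,
                      window = window)
}

#' Build an angle series directly from a theta signal
#'
#' Utility for simulation and testing: wraps an already-computed rotation
#' angle signal (degrees) with the same slope estimator [angle_series()] uses.
#'
#' @param theta_deg numeric vector of angles in `[0, 180]` (`NA` allowed).
#' @param fps frames per second.
#' @param window slope window in frames.
#' @export
angle_series_from_theta <- function(theta_deg, fps = 30, window = 5L) {
  if (length(theta_deg) < window)
    stop("short-series error: fewer frames than the slope window")
  .build_angle_series(as.numeric(theta_deg), fps = fps,
                      time_s = (seq_along(theta_deg) - 1) / fps,
                      window = window)
}

.build_angle_series <- function(theta, fps, time_s, window) {
  n <- length(theta)
  h <- window %/% 2L
  x <- seq_len(n)
  slope <- rep(NA_real_, n)
  for (i in x) {
    w <- max(1L, i - h):min(n, i + h)
    w <- w[!is.na(theta[w])]
    if (length(w) >= 2L) {
      xm <- w - mean(w)
      slope[i] <- sum(xm * theta[w]) / sum(xm^2)
    }
  }
  structure(
    data.frame(frame = x - 1L, time_s = time_s, theta_deg = theta,
               slope_deg_per_frame = slope),
    fps = fps, window = window, class = c("angle_series", "data.frame"))
}

# Interpolate interior NA runs of length <= max_gap; longer runs (and
# leading/trailing NAs) are left NA.
.bridge_gaps <- function(theta, max_gap) {
  if (!anyNA(theta)) return(theta)
  n <- length(theta)
  r <- rle(is.na(theta))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    a <- starts[k]; b <- ends[k]
    if (a == 1L || b == n || (b - a + 1L) > max_gap) next
    theta[a:b] <- theta[a - 1L] +
      (theta[b + 1L] - theta[a - 1L]) * (seq_len(b - a + 1L)) / (b - a + 2L)
  }
  theta
}

#' Per-frame movement phase labels
#'
#' Classifies every frame into the three rotation phases: `"increase"` when
#' the slope exceeds `deadband` (deg/frame), `"decrease"` below `-deadband`,
#' `"maintain"` otherwise (a slope of exactly +/-deadband is maintain).
#'
#' @param series an [angle_series()].
#' @param deadband slope magnitude treated as no directed motion (deg/frame).
#' @return Character vector, one label per frame (`NA` where slope is `NA`).
#' @export
classify_phases <- function(series, deadband = 1) {
  s <- series$slope_deg_per_frame
  out <- rep(NA_character_, length(s))
  out[!is.na(s) & s > deadband] <- "increase"
  out[!is.na(s) & s < -deadband] <- "decrease"
  out[!is.na(s) & abs(s) <= deadband] <- "maintain"
  out
}

#' Segment an angle series into full rotations
#'
#' A full rotation is one half-excursion in each direction (nominally
#' 0 -> 180 -> 0 degrees). Direction per frame is the sign of the 5-frame
#' slope, with magnitudes within `deadband` treated as "maintain". A reversal
#' is the first frame where the (nonzero) direction changes; the excursion
#' boundary is then refined to the local extremum of theta between the last
#' frame of the old direction and the first frame of the new one (the slope
#' window lags the signal, so the extremum, not the reversal frame, carries
#' the amplitude). Half-excursions smaller than `amp_min` are merged into
#' their neighbours; surviving opposite-signed half-excursions are paired in
#' temporal order, and a trailing unpaired half-excursion (an incomplete
#' rotation) yields no event. Gaps in theta longer than the interpolation
#' limit split the series: no rotation spans a split.
#'
#' @param series an [angle_series()].
#' @param amp_min minimum half-excursion amplitude in degrees (default 60,
#'   low enough to keep reduced-amplitude rotations).
#' @param deadband slope deadband in deg/frame (default 1).
#' @return Data frame of rotation events: `start_frame`, `end_frame`,
#'   `duration_s`, `excursion_deg` (sum of the two half-excursion
#'   magnitudes), `half1_deg`, `half2_deg` (signed).
#' @export
segment_rotations <- function(series, amp_min = 60, deadband = 1) {
  stopifnot(inherits(series, "angle_series"))
  fps <- attr(series, "fps")
  theta <- series$theta_deg
  slope <- series$slope_deg_per_frame
  ok <- !is.na(theta) & !is.na(slope)
  events <- list()
  r <- rle(ok)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    idx <- starts[k]:ends[k]
    ev <- .segment_chunk(theta[idx], slope[idx], amp_min, deadband,
                         margin = attr(series, "window"))
    if (!is.null(ev)) {
      ev$start_frame <- ev$start_frame + idx[1] - 2L  # to 0-based global
      ev$end_frame <- ev$end_frame + idx[1] - 2L
      events[[length(events) + 1L]] <- ev
    }
  }
  if (!length(events))
    return(data.frame(start_frame = integer(0), end_frame = integer(0),
                      duration_s = numeric(0), excursion_deg = numeric(0),
                      half1_deg = numeric(0), half2_deg = numeric(0)))
  out <- do.call(rbind, events)
  out$duration_s <- (out$end_frame - out$start_frame) / fps
  rownames(out) <- NULL
  out
}

# Segment one contiguous chunk (1-based local frames). Returns NULL or a
# data.frame with local 1-based start/end frames. The opening/closing anchor
# windows stop `margin` frames beyond the outermost directed-motion frames:
# on long motionless stretches theta is flat and its extremum carries no
# boundary information (under noise it would land anywhere in the stretch).
.segment_chunk <- function(theta, slope, amp_min, deadband, margin = 5L) {
  n <- length(theta)
  dir <- integer(n)
  dir[slope > deadband] <- 1L
  dir[slope < -deadband] <- -1L
  nz <- which(dir != 0L)
  if (!length(nz)) return(NULL)
  d <- dir[nz]
  flips <- which(d[-1] != d[-length(d)])       # reversal: d changes sign
  lo <- max(1L, nz[1] - margin)
  hi <- min(n, nz[length(nz)] + margin)
  # Anchor frames: local extrema separating half-excursions.
  anchors <- integer(0)
  first_dir <- d[1]
  # opening anchor: extremum of the opening swing's start side
  open_win <- lo:(if (length(flips)) nz[flips[1]] else hi)
  anchors <- c(anchors, .argext(theta, open_win, peak = first_dir < 0L))
  if (length(flips)) {
    for (j in seq_along(flips)) {
      a <- nz[flips[j]]          # last frame of old direction
      b <- nz[flips[j] + 1L]     # first frame of new direction
      prev_dir <- d[flips[j]]
      anchors <- c(anchors, .argext(theta, a:b, peak = prev_dir > 0L))
    }
    last_dir <- d[length(d)]
    close_win <- nz[flips[length(flips)] + 1L]:hi
  } else {
    last_dir <- first_dir
    close_win <- nz[1]:hi
  }
  anchors <- c(anchors, .argext(theta, close_win, peak = last_dir > 0L))
  anchors <- anchors[!duplicated(anchors)]
  anchors <- sort(anchors)
  anchors <- .prune_anchors(theta, anchors, amp_min)
  m <- length(anchors) - 1L                    # number of half-excursions
  if (m < 2L) return(NULL)
  amp <- diff(theta[anchors])
  n_events <- m %/% 2L
  k <- seq_len(n_events)
  data.frame(
    start_frame = anchors[2L * k - 1L],
    end_frame = anchors[2L * k + 1L],
    duration_s = NA_real_,
    excursion_deg = abs(amp[2L * k - 1L]) + abs(amp[2L * k]),
    half1_deg = amp[2L * k - 1L],
    half2_deg = amp[2L * k])
}

.argext <- function(theta, win, peak) {
  if (peak) win[which.max(theta[win])] else win[which.min(theta[win])]
}

# Drop sub-amplitude half-excursions: interior small swings merge their two
# neighbours (remove the swing's anchor pair); boundary small swings shed
# their outer anchor. Smallest swing first, repeat until all survive.
.prune_anchors <- function(theta, anchors, amp_min) {
  repeat {
    m <- length(anchors) - 1L
    if (m < 1L) return(anchors)
    amp <- abs(diff(theta[anchors]))
    j <- which.min(amp)
    if (amp[j] >= amp_min) return(anchors)
    if (j == 1L) {
      anchors <- anchors[-1L]
    } else if (j == m) {
      anchors <- anchors[-(m + 1L)]
    } else {
      anchors <- anchors[-c(j, j + 1L)]
    }
  }
}
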