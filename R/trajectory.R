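# Domain containers and file I/O for 21-landmark hand trajectories and
# participant rosters.
#
# A trajectory is stored column-wise: an n x 63 coordinate matrix with columns
# x0,y0,z0,...,x20,y20,z20 (camera coordinates: x right, y up, z toward the
# camera, in the landmark estimator's normalized units) plus frame_index and
# time_s vectors. Landmark 0 is the wrist, landmark 4 the thumb tip.

#' Number of hand landmarks per frame
#' @export
N_LANDMARKS <- 21L

.coord_names <- function() {
  as.vector(t(outer(0:(N_LANDMARKS - 1L), c("x", "y", "z"),
                    function(i, a) paste0(a, i))))
}

#' Construct a hand trajectory
#'
#' @param coords numeric matrix with one row per frame and 63 columns
#'   (`x0,y0,z0,...,x20,y20,z20`), or an n x 21 x 3 array.
#' @param fps nominal frames per second (default 30).
#' @param hand `"left"` or `"right"`.
#' @param time_s optional per-frame timestamps (seconds from trial start);
#'   synthesized as `frame_index / fps` when absent.
#' @param frame_index optional non-negative integer frame indices.
#' @param duration_s trial length in seconds; defaults to `nrow(coords) / fps`.
#'
#' @return An object of class `hand_trajectory`.
#' @export
hand_trajectory <- function(coords, fps = 30, hand = c("right", "left"),
                            time_s = NULL, frame_index = NULL,
                            duration_s = NULL) {
  hand <- match.arg(hand)
  if (is.array(coords) && length(dim(coords)) == 3L) {
    stopifnot(dim(coords)[2] == N_LANDMARKS, dim(coords)[3] == 3L)
    coords <- matrix(aperm(coords, c(1, 3, 2)), nrow = dim(coords)[1])
  }
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L * N_LANDMARKS)
    stop("schema error: expected ", 3L * N_LANDMARKS,
         " coordinate columns (21 landmarks x 3), got ", ncol(coords))
  if (nrow(coords) > 0 && !all(is.finite(coords)))
    stop("all landmark coordinates must be finite; first bad row: ",
         which(!apply(is.finite(coords), 1, all))[1])
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0)
    stop("fps must be a positive scalar")
  n <- nrow(coords)
  if (is.null(frame_index)) frame_index <- seq_len(n) - 1L
  frame_index <- as.integer(frame_index)
  if (any(frame_index < 0L)) stop("frame_index must be non-negative")
  if (is.unsorted(frame_index, strictly = TRUE))
    stop("frames must be strictly ordered by frame_index")
  if (is.null(time_s)) time_s <- frame_index / fps
  if (length(time_s) != n) stop("time_s length must match frame count")
  if (n > 1 && any(diff(time_s) < 0))
    stop("time_s must be non-decreasing with frame_index")
  if (is.null(duration_s)) duration_s <- n / fps
  if (duration_s <= 0) stop("duration_s must be positive")
  if (abs(n - fps * duration_s) > 1 + 1e-9)
    stop("frame count (", n, ") inconsistent with fps x duration (",
         fps * duration_s, "): differs by more than one frame")
  colnames(coords) <- .coord_names()
  structure(
    list(hand = hand, fps = fps, duration_s = duration_s,
         frame_index = frame_index, time_s = as.numeric(time_s),
         coords = coords),
    class = "hand_trajectory")
}

#' @export
print.hand_trajectory <- function(x, ...) {
  cat(sprintf("<hand_trajectory> %s hand, %d frames @ %g fps, %.2f s\n",
              x$hand, nrow(x$coords), x$fps, x$duration_s))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `hand_trajectory`.
#' @export
n_frames <- function(traj) nrow(traj$coords)

#' Extract one frame's landmark matrix
#'
#' @param traj a `hand_trajectory`.
#' @param i frame position (1-based).
#' @return 21 x 3 matrix of landmark positions (rows ordered landmark 0..20).
#' @export
landmark_frame <- function(traj, i) {
  stopifnot(i >= 1L, i <= n_frames(traj))
  matrix(traj$coords[i, ], ncol = 3L, byrow = TRUE,
         dimnames = list(NULL, c("x", "y", "z")))
}

#' Read a trajectory CSV
#'
#' Expects the long per-trial dialect written by [write_trajectory()]:
#' columns `frame`, optionally `time_s`, then `x0,y0,z0,...,x20,y20,z20`.
#' Missing timestamps are synthesized as `frame / fps`.
#'
#' @param path CSV file path.
#' @param fps nominal frames per second used when `time_s` is absent.
#' @param hand hand label; defaults to a `hand` attribute column-comment-free
#'   guess from the filename (`*_left_*` / `*_right_*`), else `"right"`.
#' @return A validated [hand_trajectory()].
#' @export
read_trajectory <- function(path, fps = 30, hand = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  want <- .coord_names()
  if (!all(want %in% names(df))) {
    missing <- setdiff(want, names(df))
    stop("schema error in ", basename(path), ": missing ", length(missing),
         " landmark coordinate columns (need 21 landmarks x 3), e.g. ",
         paste(utils::head(missing, 3), collapse = ", "))
  }
  if (!"frame" %in% names(df)) stop("schema error: no 'frame' column")
  coords <- suppressWarnings(
    matrix(as.numeric(as.matrix(df[, want])), nrow = nrow(df)))
  if (nrow(coords) > 0) {
    bad <- which(!apply(coords, 1, function(r) all(is.finite(r))))
    if (length(bad))
      stop("parse error in ", basename(path), ": non-numeric or non-finite ",
           "coordinates at data row ", bad[1])
  }
  if (is.null(hand)) {
    hand <- if (grepl("(^|[_.-])left([_.-]|$)", basename(path))) "left"
            else "right"
  }
  time_s <- if ("time_s" %in% names(df)) as.numeric(df$time_s) else NULL
  hand_trajectory(coords, fps = fps, hand = hand, time_s = time_s,
                  frame_index = as.integer(df$frame))
}

#' Write a trajectory CSV
#'
#' Writes the long dialect read by [read_trajectory()]. Coordinates are
#' serialized with 17 significant digits so a read/write round trip is exact
#' and output is byte-stable for identical input.
#'
#' @param traj a `hand_trajectory`.
#' @param path destination file.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "hand_trajectory"))
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot write ", path, ": ", conditionMessage(e)))
  on.exit(close(con))
  header <- c("frame", "time_s", .coord_names())
  writeLines(paste(header, collapse = ","), con)
  n <- n_frames(traj)
  if (n > 0) {
    num <- function(v) sprintf("%.17g", v)
    rows <- paste(traj$frame_index,
                  num(traj$time_s),
                  apply(traj$coords, 1, function(r) paste(num(r), collapse = ",")),
                  sep = ",")
    writeLines(rows, con)
  }
  invisible(path)
}

# ---- roster ----------------------------------------------------------------

.roster_required <- c("participant_id", "group", "age", "gender",
                      "dominant_hand", "education")

#' Validate a participant roster
#'
#' Checks the invariants used throughout the pipeline: unique anonymized ids,
#' group-consistent ages (young 20-29, older 65-80), valid factor levels and
#' non-negative integer pegboard scores.
#'
#' @param roster data frame with columns `participant_id`, `group`
#'   (`young`/`older`), `age`, `gender` (`male`/`female`), `dominant_hand`
#'   (`left`/`right`), `education`, and pegboard columns `ppt_1..ppt_3`
#'   (NA allowed).
#' @return The roster, invisibly coerced (group/gender/hand as character).
#' @export
validate_roster <- function(roster) {
  roster <- as.data.frame(roster)
  missing <- setdiff(.roster_required, names(roster))
  if (length(missing))
    stop("roster missing columns: ", paste(missing, collapse = ", "))
  errs <- character(0)
  dup <- roster$participant_id[duplicated(roster$participant_id)]
  if (length(dup))
    errs <- c(errs, paste0("duplicate participant_id: ",
                           paste(unique(dup), collapse = ", ")))
  bad_grp <- !roster$group %in% c("young", "older")
  if (any(bad_grp))
    errs <- c(errs, paste0("unknown group for: ",
                           paste(roster$participant_id[bad_grp], collapse = ", ")))
  young_bad <- roster$group == "young" & (roster$age < 20 | roster$age > 29)
  older_bad <- roster$group == "older" & (roster$age < 65 | roster$age > 80)
  bad_age <- (young_bad | older_bad) & !bad_grp
  if (any(bad_age, na.rm = TRUE))
    errs <- c(errs, paste0("age outside group range for: ",
                           paste(roster$participant_id[which(bad_age)],
                                 collapse = ", ")))
  if (any(!roster$gender %in% c("male", "female")))
    errs <- c(errs, "gender must be male/female")
  if (any(!roster$dominant_hand %in% c("left", "right")))
    errs <- c(errs, "dominant_hand must be left/right")
  ppt_cols <- grep("^ppt_[0-9]+$", names(roster), value = TRUE)
  if (length(ppt_cols)) {
    ppt <- as.matrix(roster[, ppt_cols, drop = FALSE])
    bad_ppt <- apply(ppt, 1, function(r) {
      r <- r[!is.na(r)]
      length(r) > 0 && (any(r < 0) || any(r != round(r)))
    })
    if (any(bad_ppt))
      errs <- c(errs, paste0("pegboard scores must be non-negative integers",
                             " for: ",
                             paste(roster$participant_id[bad_ppt],
                                   collapse = ", ")))
  }
  if (length(errs)) stop("roster validation failed:\n  ",
                         paste(errs, collapse = "\n  "))
  for (col in c("participant_id", "group", "gender", "dominant_hand",
                "education"))
    roster[[col]] <- as.character(roster[[col]])
  roster
}

#' Read a participant roster CSV
#'
#' @param path CSV with the columns described in [validate_roster()].
#' @return Validated roster data frame.
#' @export
read_roster <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  validate_roster(utils::read.csv(path))
}

#' Write a participant roster CSV
#' @param roster validated roster data frame.
#' @param path destination file.
#' @export
write_roster <- function(roster, path) {
  utils::write.csv(validate_roster(roster), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a trial recording
#'
#' Binds a trajectory to its (participant, hand, trial) cell; the unit the
#' metrics table is built from.
#'
#' @param participant_id anonymized id.
#' @param hand `"left"` or `"right"` (must match the trajectory's label).
#' @param trial trial number 1, 2 or 3.
#' @param trajectory a `hand_trajectory`.
#' @export
trial_recording <- function(participant_id, hand, trial, trajectory) {
  stopifnot(inherits(trajectory, "hand_trajectory"))
  trial <- as.integer(trial)
  if (!trial %in% 1:3) stop("trial must be 1, 2 or 3")
  hand <- match.arg(hand, c("left", "right"))
  if (hand != trajectory$hand)
    stop("recording hand label disagrees with trajectory hand")
  structure(list(participant_id = as.character(participant_id),
                 hand = hand, trial = trial, trajectory = trajectory),
            class = "trial_recording")
}
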