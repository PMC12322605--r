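# End-to-end orchestration: configuration, extraction from per-trial
# trajectory files, the statistical stage, and a fully simulated run.

#' Run configuration
#'
#' Bundles every tunable parameter of the pipeline with its default, so a
#' run is reproducible from the config and seed alone. Serializable with
#' [save_config()] / [load_config()].
#'
#' @param fps frames per second of the recordings (default 30).
#' @param trial_duration_s trial length in seconds (default 10).
#' @param window_frames slope estimation window (default 5).
#' @param deadband_deg_per_frame slope deadband for the maintain phase.
#' @param amp_min_deg minimum half-excursion amplitude (degrees).
#' @param max_gap_frames longest degenerate gap bridged by interpolation.
#' @param k_sd pegboard screening band half-width in SD units.
#' @param alpha significance level for the analysis stage.
#' @param corstr working correlation structure.
#' @param seed integer seed for simulated stages.
#' @export
run_config <- function(fps = 30, trial_duration_s = 10, window_frames = 5L,
                       deadband_deg_per_frame = 1, amp_min_deg = 60,
                       max_gap_frames = 5L, k_sd = 2, alpha = 0.05,
                       corstr = "exchangeable", seed = 1L) {
  cfg <- list(fps = fps, trial_duration_s = trial_duration_s,
              window_frames = as.integer(window_frames),
              deadband_deg_per_frame = deadband_deg_per_frame,
              amp_min_deg = amp_min_deg,
              max_gap_frames = as.integer(max_gap_frames),
              k_sd = k_sd, alpha = alpha, corstr = corstr,
              seed = as.integer(seed))
  stopifnot(cfg$fps > 0, cfg$trial_duration_s > 0, cfg$window_frames >= 2L,
            cfg$deadband_deg_per_frame >= 0, cfg$amp_min_deg > 0,
            cfg$max_gap_frames >= 0L, cfg$k_sd > 0,
            cfg$alpha > 0, cfg$alpha < 1,
            cfg$corstr %in% c("exchangeable", "independence", "ar1"))
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path JSON file path.
#' @export
save_config <- function(config, path) {
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA), path)
  invisible(path)
}

#' @rdname run_config
#' @export
load_config <- function(path) {
  do.call(run_config, jsonlite::fromJSON(path))
}

#' Extract the cohort metrics table from trajectory files
#'
#' Reads and screens the roster, then loads every per-trial trajectory file
#' named `<participant>_<hand>_<trial>.csv` under `trajectory_dir` for the
#' included participants and computes the seven indicators per trial.
#' Unreadable files are skipped with a warning and surface in the table's
#' `missing` attribute.
#'
#' @param trajectory_dir directory of per-trial trajectory CSVs.
#' @param roster roster data frame or path to a roster CSV.
#' @param config a [run_config()].
#' @param out_csv optional path: write the dataset plus a JSON sidecar
#'   (`<out_csv>.meta.json`) recording the config.
#' @return The metrics table (see [metrics_table()]); attributes `screen`
#'   (the screening result) and `missing`.
#' @export
run_extract <- function(trajectory_dir, roster, config = run_config(),
                        out_csv = NULL) {
  if (is.character(roster) && length(roster) == 1L) roster <- read_roster(roster)
  scr <- screen_participants(roster, k_sd = config$k_sd)
  inc <- scr$included
  recs <- list()
  for (pid in inc$participant_id) for (hand in c("left", "right"))
    for (trial in 1:3) {
      f <- file.path(trajectory_dir, sprintf("%s_%s_%d.csv", pid, hand, trial))
      if (!file.exists(f)) next
      rec <- tryCatch(
        trial_recording(pid, hand, trial,
                        read_trajectory(f, fps = config$fps, hand = hand)),
        error = function(e) {
          warning("skipping unreadable trial ", basename(f), ": ",
                  conditionMessage(e))
          NULL
        })
      if (!is.null(rec)) recs[[length(recs) + 1L]] <- rec
    }
  tab <- metrics_table(recs, inc, window = config$window_frames,
                       deadband = config$deadband_deg_per_frame,
                       amp_min = config$amp_min_deg,
                       max_gap = config$max_gap_frames)
  if (!is.null(out_csv)) {
    utils::write.csv(tab, out_csv, row.names = FALSE, quote = FALSE)
    meta <- list(config = unclass(config),
                 n_included = nrow(inc), n_excluded = nrow(scr$excluded),
                 n_rows = nrow(tab), n_missing_cells = nrow(attr(tab, "missing")))
    writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
               paste0(out_csv, ".meta.json"))
  }
  attr(tab, "screen") <- scr
  tab
}

#' Run the statistical stage on a cohort dataset
#'
#' @param dataset long-format metrics table (data frame or CSV path).
#' @param config a [run_config()].
#' @param out_json optional path for the JSON report.
#' @return An [analysis_report()] object.
#' @export
run_analyze <- function(dataset, config = run_config(), out_json = NULL) {
  if (is.character(dataset) && length(dataset) == 1L)
    dataset <- utils::read.csv(dataset)
  need <- c("participant_id", "group", "hand", "trial")
  if (!all(need %in% names(dataset)))
    stop("schema error: dataset lacks column(s) ",
         paste(setdiff(need, names(dataset)), collapse = ", "))
  rep <- analysis_report(dataset, alpha = config$alpha,
                         corstr = config$corstr)
  if (!is.null(out_json)) report_json(rep, out_json)
  rep
}

#' Simulate, extract and analyze in one call
#'
#' Demo-scale end-to-end run: simulates a roster and per-trial trajectory
#' files (rotation tempo/amplitude varied by group), extracts the metrics
#' table, runs the analysis, and writes every artifact plus a manifest with
#' file hashes, the seed and the config.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @param n_young,n_older simulated group sizes (demo default 6/6).
#' @return Invisible list with `dataset`, `report` and `manifest`.
#' @export
run_all <- function(config = run_config(), out_dir, n_young = 6L,
                    n_older = 6L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  traj_dir <- file.path(out_dir, "trajectories")
  dir.create(traj_dir, showWarnings = FALSE)
  set.seed(config$seed)
  roster <- make_roster(n_young = n_young, n_older = n_older)
  roster_path <- file.path(out_dir, "roster.csv")
  write_roster(roster, roster_path)
  tempo <- stats::rnorm(nrow(roster), 0, 0.05)  # per-participant pace
  for (i in seq_len(nrow(roster))) {
    young <- roster$group[i] == "young"
    for (hand in c("left", "right")) for (trial in 1:3) {
      prof <- motion_profile(
        base_amplitude_deg = if (young) 170 else 120,
        base_period_s = max(0.3, (if (young) 0.45 else 0.62) + tempo[i]),
        n_rotations_target = 40L,
        period_drift_per_rotation_s = -0.002,
        angle_noise_sd_deg = 2,
        seed = config$seed + 1000L * i + 10L * trial +
          as.integer(hand == "left"))
      sim <- make_trajectory(prof, fps = config$fps,
                             duration_s = config$trial_duration_s,
                             hand = hand)
      write_trajectory(sim$trajectory,
                       file.path(traj_dir, sprintf("%s_%s_%d.csv",
                                                   roster$participant_id[i],
                                                   hand, trial)))
    }
  }
  dataset_path <- file.path(out_dir, "metrics.csv")
  tab <- run_extract(traj_dir, roster_path, config, out_csv = dataset_path)
  report_path <- file.path(out_dir, "report.json")
  rep <- run_analyze(tab, config, out_json = report_path)
  cfg_path <- file.path(out_dir, "config.json")
  save_config(config, cfg_path)
  files <- c(roster_path, dataset_path, report_path, cfg_path,
             list.files(traj_dir, full.names = TRUE))
  manifest <- data.frame(file = sub(paste0("^", out_dir, "/?"), "", files),
                         md5 = unname(tools::md5sum(files)))
  manifest_path <- file.path(out_dir, "manifest.json")
  writeLines(jsonlite::toJSON(list(seed = config$seed,
                                   config = unclass(config),
                                   files = manifest),
                              dataframe = "rows", auto_unbox = TRUE,
                              digits = NA),
             manifest_path)
  invisible(list(dataset = tab, report = rep, manifest = manifest))
}
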