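#!/usr/bin/env Rscript
# Step 1 — simulate the study's raw material at demo scale: a screened
# roster and per-trial landmark trajectory files (both hands, 3 trials,
# 10 s at 30 fps), with older participants programmed to rotate slower and
# with smaller amplitude; plus a full-size (29 + 39) metric-level cohort
# with the reference group means, trial learning shifts and exchangeable
# within-participant correlation.

suppressPackageStartupMessages(library(handrot))

cfg <- run_config(seed = 20260101L)
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

message("Simulating demo cohort (6 young + 6 older) with trajectories ...")
res <- run_all(cfg, out, n_young = 6L, n_older = 6L)
message(sprintf("  wrote %d trajectory files, roster, metrics and manifest under %s",
                sum(grepl("^trajectories/", res$manifest$file)), out))

message("Simulating full-size metric-level cohort (29 young + 39 older) ...")
cohort <- simulate_cohort(cohort_spec(seed = cfg$seed + 1L))
write.csv(cohort, "results/cohort_metrics.csv", row.names = FALSE,
          quote = FALSE)
message(sprintf("  %d rows (%d participants x 2 hands x 3 trials) -> results/cohort_metrics.csv",
                nrow(cohort), length(unique(cohort$participant_id))))
message(sprintf("  young mean rotation count %.2f vs older %.2f",
                mean(cohort$total_rotation_count[cohort$group == "young"]),
                mean(cohort$total_rotation_count[cohort$group == "older"])))
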