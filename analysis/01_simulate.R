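#!/usr/bin/env Rscript
# Stage 1 — simulate the longitudinal habituation study.
#
# Generates the full synthetic cohort under the default study conditions:
# 68 controls and 70 early-psychosis patients, two visits two years apart,
# three regions (anterior hippocampus, occipital pole, FFA), one analyzed
# 2-min repetition run per visit with 1 Hz stimuli, 10% small-image targets
# (none in the first 10 s), a novelty peak at 8 s decaying linearly to
# baseline by 18 s, AR(1) volume noise, correlated hemispheres, and
# occasional global-intensity spike artifacts.

suppressMessages(library(habslope))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 2 && args[1] == "--seed") as.integer(args[2]) else 1L
run_dir <- "results/run"
dir.create(run_dir, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = seed)
sim <- simulate_cohort(cfg)

write.csv(sim$cohort, file.path(run_dir, "cohort.csv"), row.names = FALSE)
write.csv(sim$timeseries, file.path(run_dir, "timeseries.csv"),
          row.names = FALSE)
write.csv(sim$runs, file.path(run_dir, "runs.csv"), row.names = FALSE)
write.csv(sim$schedules, file.path(run_dir, "schedules.csv"),
          row.names = FALSE)
write.csv(sim$ground_truth$slopes,
          file.path(run_dir, "ground_truth_slopes.csv"), row.names = FALSE)
yaml::write_yaml(list(seed = seed), file.path(run_dir, "seed.yaml"))

gt <- sim$ground_truth$slopes
cat(sprintf("Simulated %d participants x %d visits x %d regions (seed %d)\n",
            cfg$n_control + cfg$n_patient, length(cfg$visits),
            length(cfg$regions), seed))
cat(sprintf("True b' cell means, anterior hippocampus: control %.3f / %.3f, patient %.3f / %.3f (baseline / follow-up)\n",
            mean(gt$true_b_prime[gt$group == "control" & gt$visit == "baseline" & gt$region == "anterior_hippocampus"]),
            mean(gt$true_b_prime[gt$group == "control" & gt$visit == "followup" & gt$region == "anterior_hippocampus"]),
            mean(gt$true_b_prime[gt$group == "patient" & gt$visit == "baseline" & gt$region == "anterior_hippocampus"]),
            mean(gt$true_b_prime[gt$group == "patient" & gt$visit == "followup" & gt$region == "anterior_hippocampus"])))
cat(sprintf("Injected %d spike artifacts across %d runs\n",
            if (is.null(sim$ground_truth$outliers)) 0L
            else nrow(sim$ground_truth$outliers),
            nrow(unique(sim$runs[, c("participant_id", "visit")]))))
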