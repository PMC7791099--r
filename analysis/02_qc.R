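#!/usr/bin/env Rscript
# Stage 2 — artifact detection.
#
# Flags outlier volumes per run with the ART-style rule: global-intensity
# change beyond 5 SD of the run's change distribution, or motion beyond
# 3 mm (absolute translation or frame-to-frame relative displacement).
# Run-level exclusion is applied later, once the habituation window is
# known (stage 4).

suppressMessages(library(habslope))

run_dir <- "results/run"
runs <- read.csv(file.path(run_dir, "runs.csv"))

keys <- unique(runs[, c("participant_id", "visit")])
rows <- vector("list", nrow(keys))
for (i in seq_len(nrow(keys))) {
  sel <- runs$participant_id == keys$participant_id[i] &
    runs$visit == keys$visit[i]
  rr <- runs[sel, ][order(runs$volume[sel]), ]
  mot <- motion_trace(as.matrix(rr[, c("trans_x", "trans_y", "trans_z",
                                       "rot_x", "rot_y", "rot_z")]))
  det <- detect_outlier_volumes(rr$global_signal, mot)
  rows[[i]] <- data.frame(participant_id = keys$participant_id[i],
                          visit = keys$visit[i],
                          n_outliers = length(det),
                          outlier_volumes = paste(det, collapse = ";"),
                          max_rel_disp_mm = max(mot$rel_displacement))
}
qc <- do.call(rbind, rows)
write.csv(qc, file.path(run_dir, "qc_outliers.csv"), row.names = FALSE)

cat(sprintf("QC over %d runs: %d runs with >=1 outlier volume (max %d), median peak displacement %.3f mm\n",
            nrow(qc), sum(qc$n_outliers > 0), max(qc$n_outliers),
            median(qc$max_rel_disp_mm)))
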