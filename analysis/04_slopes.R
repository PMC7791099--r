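#!/usr/bin/env Rscript
# Stage 4 — run exclusion and habituation slopes.
#
# Runs with two or more outlier volumes inside the habituation window are
# excluded. For every remaining participant x region x visit the novelty
# amplitude (signal at window start), the raw OLS slope over the window,
# and the novelty-normalized slope b' = b / a are computed; more negative
# b' means faster habituation.

suppressMessages(library(habslope))

run_dir <- "results/run"
resid <- read.csv(file.path(run_dir, "residual_timeseries.csv"))
qc <- read.csv(file.path(run_dir, "qc_outliers.csv"),
               colClasses = c(outlier_volumes = "character"))
wj <- jsonlite::read_json(file.path(run_dir, "window.json"),
                          simplifyVector = TRUE)
win <- habituation_window(wj$t_peak_s, wj$t_return_s, wj$tr_seconds)
nv <- length(unique(resid$volume))

qc$n_outliers_in_window <- NA_integer_
qc$excluded <- NA
for (i in seq_len(nrow(qc))) {
  outliers <- if (nzchar(qc$outlier_volumes[i]))
    as.integer(strsplit(qc$outlier_volumes[i], ";")[[1]]) else integer(0)
  rep_i <- apply_exclusion_rule(outliers, win, n_volumes = nv)
  qc$n_outliers_in_window[i] <- rep_i$n_outliers_in_window
  qc$excluded[i] <- rep_i$excluded
}
write.csv(qc, file.path(run_dir, "qc_report.csv"), row.names = FALSE)

keep_key <- paste(qc$participant_id, qc$visit)[!qc$excluded]
keep <- paste(resid$participant_id, resid$visit) %in% keep_key
slopes <- compute_slopes(resid[keep, ], win, wj$tr_seconds)
write.csv(slopes, file.path(run_dir, "slopes.csv"), row.names = FALSE)

cat(sprintf("Excluded %d of %d runs (>=2 outlier volumes in the %g s window)\n",
            sum(qc$excluded), nrow(qc), win$duration_s))
agg <- aggregate(b_prime ~ group + visit + region, slopes, mean)
cat("Mean b' by cell:\n")
print(agg, row.names = FALSE)
cat(sprintf("%d slope estimates flagged unreliable (novelty amplitude near zero)\n",
            sum(slopes$unreliable)))
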