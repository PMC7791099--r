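#!/usr/bin/env Rscript
# Stage 6 — human-readable report.
#
# Renders the within-group habituation table (mean ± SD, t, df, p) and the
# region-wise mixed-model table from the run summary, starring entries
# significant at alpha = 0.05.

suppressMessages(library(habslope))

run_dir <- "results/run"
lines <- make_report(run_dir)
cat(lines, sep = "\n")
cat("\nReport written to", file.path(run_dir, "report.txt"), "\n")
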