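#!/usr/bin/env Rscript
# Stage 3 — first-level residualization, hemisphere averaging, and
# habituation-window detection.
#
# Each ROI series is residualized against its run's nuisance design
# (intercept, 6 motion parameters, relative displacement, one spike
# regressor per flagged outlier volume, a boxcar over small-image targets;
# no temporal filter). Left and right hemispheres are then averaged — they
# are simulated, as observed empirically, to be highly correlated. Finally
# the habituation window is detected from the baseline-visit control-group
# mean: peak of the novelty response to first return to baseline.

suppressMessages(library(habslope))

run_dir <- "results/run"
ts <- read.csv(file.path(run_dir, "timeseries.csv"))
runs <- read.csv(file.path(run_dir, "runs.csv"))
sched <- read.csv(file.path(run_dir, "schedules.csv"))
qc <- read.csv(file.path(run_dir, "qc_outliers.csv"),
               colClasses = c(outlier_volumes = "character"))
tr <- diff(sort(unique(ts$time_s)))[1]
nv <- length(unique(ts$volume))

cells <- unique(ts[, c("participant_id", "group", "visit", "region")])
out <- vector("list", nrow(cells))
cors <- numeric(nrow(cells))
for (i in seq_len(nrow(cells))) {
  pid <- cells$participant_id[i]; vis <- cells$visit[i]
  sel <- runs$participant_id == pid & runs$visit == vis
  rr <- runs[sel, ][order(runs$volume[sel]), ]
  qrow <- qc[qc$participant_id == pid & qc$visit == vis, ]
  outliers <- if (nzchar(qrow$outlier_volumes))
    as.integer(strsplit(qrow$outlier_volumes, ";")[[1]]) else integer(0)
  ss <- sched[sched$participant_id == pid & sched$visit == vis, ]
  X <- build_nuisance_design(
    as.matrix(rr[, c("trans_x", "trans_y", "trans_z",
                     "rot_x", "rot_y", "rot_z")]),
    outliers = outliers, target_onsets = ss$onset_s[ss$is_target],
    n_volumes = nv, tr_seconds = tr)
  hemi <- lapply(c("left", "right"), function(h) {
    sub <- ts[ts$participant_id == pid & ts$visit == vis &
                ts$region == cells$region[i] & ts$hemisphere == h, ]
    roi_timeseries(residualize(sub$signal[order(sub$volume)], X), tr,
                   pid, cells$group[i], vis, cells$region[i], h)
  })
  avg <- suppressWarnings(average_hemispheres(hemi[[1]], hemi[[2]]))
  cors[i] <- avg$correlation
  out[[i]] <- data.frame(participant_id = pid, group = cells$group[i],
                         visit = vis, region = cells$region[i],
                         volume = seq_len(nv) - 1L,
                         time_s = (seq_len(nv) - 1L) * tr,
                         signal = avg$series$signal)
}
resid <- do.call(rbind, out)
write.csv(resid, file.path(run_dir, "residual_timeseries.csv"),
          row.names = FALSE)
cat(sprintf("Residualized %d runs x regions; median left/right correlation %.2f\n",
            nrow(cells), median(cors)))

ctl <- resid[resid$group == "control" & resid$visit == "baseline", ]
cm <- tapply(ctl$signal, ctl$volume, mean)
win <- detect_window(as.numeric(cm[order(as.integer(names(cm)))]), tr)
jsonlite::write_json(unclass(win)[c("t_peak_s", "t_return_s", "start_index",
                                    "end_index", "duration_s",
                                    "tr_seconds")],
                     file.path(run_dir, "window.json"), auto_unbox = TRUE,
                     digits = NA)
cat(sprintf("Habituation window from baseline controls: [%g, %g] s (%g s, volumes %d..%d)\n",
            win$t_peak_s, win$t_return_s, win$duration_s, win$start_index,
            win$end_index))
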