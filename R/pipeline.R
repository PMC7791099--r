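#' Pipeline configuration
#'
#' Bundles the simulation settings, QC thresholds, window source and
#' statistics options that drive [run_pipeline()]. Every run writes a
#' snapshot of this configuration alongside its outputs.
#'
#' @param sim a [sim_config()].
#' @param qc_sd_mult global-intensity-change threshold (SD units).
#' @param qc_motion_mm motion threshold (mm).
#' @param qc_max_in_window run-exclusion threshold: outlier volumes inside
#'   the habituation window.
#' @param window_source `"detect"` (from baseline controls) or `"fixed"`.
#' @param fixed_window numeric `c(t_peak_s, t_return_s)` used when
#'   `window_source = "fixed"`.
#' @param ddf denominator-df method for the mixed model.
#' @param fwe_method familywise correction for the correlation screen.
#' @param alpha significance threshold.
#' @param seed global seed; overrides `sim$seed`.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(sim = sim_config(), qc_sd_mult = 5,
                            qc_motion_mm = 3, qc_max_in_window = 2,
                            window_source = c("detect", "fixed"),
                            fixed_window = c(8, 18),
                            ddf = "between-within", fwe_method = "holm",
                            alpha = 0.05, seed = sim$seed) {
  window_source <- match.arg(window_source)
  stopifnot(qc_sd_mult > 0, qc_motion_mm > 0, qc_max_in_window >= 1,
            alpha > 0, alpha < 1)
  if (window_source == "fixed") {
    stopifnot(length(fixed_window) == 2, fixed_window[1] > 0,
              fixed_window[2] > fixed_window[1])
  }
  sim$seed <- as.integer(seed)
  structure(list(sim = validate_sim_config(sim), qc_sd_mult = qc_sd_mult,
                 qc_motion_mm = qc_motion_mm,
                 qc_max_in_window = qc_max_in_window,
                 window_source = window_source, fixed_window = fixed_window,
                 ddf = ddf, fwe_method = fwe_method, alpha = alpha,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognized top-level sections: `cohort` (n_control, n_patient, visits,
#' regions), `signal` (tr_seconds, run_duration_s, soa_s, target_fraction,
#' peak_time_s, return_time_s, novelty_mean, novelty_sd, slope_sd),
#' `noise` (noise_sd, ar1_coef, hemi_correlation, outlier_rate),
#' `qc` (sd_mult, motion_mm, max_in_window), `window` (source, t_peak_s,
#' t_return_s), `stats` (ddf, fwe_method, alpha), and `seed`. Missing keys
#' fall back to the package defaults.
#'
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  simargs <- c(y$cohort, y$signal, y$noise)
  simargs <- simargs[names(simargs) %in% names(formals(sim_config))]
  sim <- do.call(sim_config, simargs)
  pipeline_config(
    sim = sim,
    qc_sd_mult = y$qc$sd_mult %||% 5,
    qc_motion_mm = y$qc$motion_mm %||% 3,
    qc_max_in_window = y$qc$max_in_window %||% 2,
    window_source = y$window$source %||% "detect",
    fixed_window = c(y$window$t_peak_s %||% 8, y$window$t_return_s %||% 18),
    ddf = y$stats$ddf %||% "between-within",
    fwe_method = y$stats$fwe_method %||% "holm",
    alpha = y$stats$alpha %||% 0.05,
    seed = y$seed %||% sim$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full habituation analysis pipeline
#'
#' simulate -> QC -> residualize & hemisphere-average -> window ->
#' slopes (with run exclusion) -> inference. Each stage writes its table
#' under `out_dir`; a machine-readable `summary.json`, a YAML config
#' snapshot and a plain-text log complete the run directory. Reruns with an
#' identical configuration and seed produce identical tables.
#'
#' @param config a [pipeline_config()].
#' @param out_dir run directory (created if needed).
#' @param write_timeseries also write the full residual time-series table
#'   (large); the summary tables never depend on this flag.
#' @return invisibly, a list with all stage outputs (`cohort`, `qc`,
#'   `residuals`, `window`, `slopes`, `models`, `within_group`,
#'   `correlations`, `demographics`, `summary`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         write_timeseries = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- config$sim
  log_lines <- c(sprintf("habslope pipeline, package %s",
                         as.character(utils::packageVersion("habslope"))),
                 sprintf("seed: %d", config$seed))
  t0 <- Sys.time()

  # -- simulate ---------------------------------------------------------
  sim <- simulate_cohort(cfg)
  utils::write.csv(sim$cohort, file.path(out_dir, "cohort.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$ground_truth$slopes,
                   file.path(out_dir, "ground_truth_slopes.csv"),
                   row.names = FALSE)
  log_lines <- c(log_lines,
                 sprintf("simulated %d participants (%d control, %d patient), %d visits, %d regions",
                         cfg$n_control + cfg$n_patient, cfg$n_control,
                         cfg$n_patient, length(cfg$visits),
                         length(cfg$regions)))

  # -- qc: outlier detection per run ------------------------------------
  nv <- n_volumes(cfg)
  run_keys <- unique(sim$runs[, c("participant_id", "visit")])
  rownames(run_keys) <- NULL
  qc_rows <- vector("list", nrow(run_keys))
  outliers_by_run <- vector("list", nrow(run_keys))
  for (i in seq_len(nrow(run_keys))) {
    sel <- sim$runs$participant_id == run_keys$participant_id[i] &
      sim$runs$visit == run_keys$visit[i]
    rr <- sim$runs[sel, ][order(sim$runs$volume[sel]), ]
    mot <- motion_trace(as.matrix(rr[, c("trans_x", "trans_y", "trans_z",
                                         "rot_x", "rot_y", "rot_z")]))
    det <- detect_outlier_volumes(rr$global_signal, mot,
                                  sd_mult = config$qc_sd_mult,
                                  motion_mm = config$qc_motion_mm)
    outliers_by_run[[i]] <- det
    qc_rows[[i]] <- data.frame(participant_id = run_keys$participant_id[i],
                               visit = run_keys$visit[i],
                               n_outliers = length(det),
                               outlier_volumes = paste(det, collapse = ";"),
                               max_rel_disp_mm = max(mot$rel_displacement))
  }
  qc_tab <- do.call(rbind, qc_rows)

  # -- extract: residualize and average hemispheres ---------------------
  ts <- sim$timeseries
  res_rows <- list()
  cells <- unique(ts[, c("participant_id", "group", "visit", "region")])
  rownames(cells) <- NULL
  for (i in seq_len(nrow(cells))) {
    pid <- cells$participant_id[i]; vis <- cells$visit[i]
    reg <- cells$region[i]
    ri <- which(run_keys$participant_id == pid & run_keys$visit == vis)
    sel <- sim$runs$participant_id == pid & sim$runs$visit == vis
    rr <- sim$runs[sel, ][order(sim$runs$volume[sel]), ]
    sched <- sim$schedules[sim$schedules$participant_id == pid &
                             sim$schedules$visit == vis, ]
    X <- build_nuisance_design(
      as.matrix(rr[, c("trans_x", "trans_y", "trans_z",
                       "rot_x", "rot_y", "rot_z")]),
      outliers = outliers_by_run[[ri]],
      target_onsets = sched$onset_s[sched$is_target],
      n_volumes = nv, tr_seconds = cfg$tr_seconds)
    hemi <- list()
    for (h in c("left", "right")) {
      sub <- ts[ts$participant_id == pid & ts$visit == vis &
                  ts$region == reg & ts$hemisphere == h, ]
      sig <- sub$signal[order(sub$volume)]
      hemi[[h]] <- roi_timeseries(residualize(sig, X), cfg$tr_seconds,
                                  pid, cells$group[i], vis, reg, h)
    }
    avg <- average_hemispheres(hemi$left, hemi$right)
    res_rows[[i]] <- data.frame(
      participant_id = pid, group = cells$group[i], visit = vis,
      region = reg, volume = seq_len(nv) - 1L,
      time_s = (seq_len(nv) - 1L) * cfg$tr_seconds,
      signal = avg$series$signal, hemi_correlation = avg$correlation)
  }
  resid_tab <- do.call(rbind, res_rows)
  if (write_timeseries)
    utils::write.csv(resid_tab, file.path(out_dir, "residual_timeseries.csv"),
                     row.names = FALSE)

  # -- window: baseline controls only -----------------------------------
  if (config$window_source == "fixed") {
    window <- habituation_window(config$fixed_window[1],
                                 config$fixed_window[2], cfg$tr_seconds)
  } else {
    base_vis <- cfg$visits[1]
    ctl <- resid_tab[resid_tab$group == "control" &
                       resid_tab$visit == base_vis, ]
    if (nrow(ctl) == 0) stop("no baseline control data to detect a window",
                             call. = FALSE)
    cm <- tapply(ctl$signal, ctl$volume, mean)
    cm <- as.numeric(cm[order(as.integer(names(cm)))])
    window <- detect_window(cm, cfg$tr_seconds)
  }
  jsonlite::write_json(unclass(window)[c("t_peak_s", "t_return_s",
                                         "start_index", "end_index",
                                         "duration_s", "tr_seconds")],
                       file.path(out_dir, "window.json"),
                       auto_unbox = TRUE, digits = NA)
  log_lines <- c(log_lines,
                 sprintf("habituation window: [%g, %g] s (volumes %d..%d)",
                         window$t_peak_s, window$t_return_s,
                         window$start_index, window$end_index))

  # -- qc exclusions under the window -----------------------------------
  qc_tab$n_outliers_in_window <- NA_integer_
  qc_tab$excluded <- NA
  for (i in seq_len(nrow(qc_tab))) {
    rep_i <- apply_exclusion_rule(outliers_by_run[[i]], window,
                                  n_volumes = nv,
                                  max_in_window = config$qc_max_in_window)
    qc_tab$n_outliers_in_window[i] <- rep_i$n_outliers_in_window
    qc_tab$excluded[i] <- rep_i$excluded
  }
  utils::write.csv(qc_tab, file.path(out_dir, "qc_report.csv"),
                   row.names = FALSE)
  log_lines <- c(log_lines,
                 sprintf("QC: %d of %d runs excluded (>=%d outliers in window)",
                         sum(qc_tab$excluded), nrow(qc_tab),
                         config$qc_max_in_window))

  # -- slopes (excluded runs dropped) -----------------------------------
  qkey <- paste(qc_tab$participant_id, qc_tab$visit)
  keep <- !qc_tab$excluded[match(paste(resid_tab$participant_id,
                                       resid_tab$visit), qkey)]
  slopes <- compute_slopes(resid_tab[keep, ], window, cfg$tr_seconds)
  utils::write.csv(slopes, file.path(out_dir, "slopes.csv"),
                   row.names = FALSE)

  # -- inference ---------------------------------------------------------
  models <- do.call(rbind, lapply(cfg$regions, function(reg)
    fit_group_time_model(slopes[slopes$region == reg, ], ddf = config$ddf,
                         region = reg)))
  attr(models, "fit") <- NULL
  within_group <- one_sample_by_cell(slopes)
  measures <- c("wtar", "scip", "panss_total", "panss_positive",
                "panss_negative", "panss_general", "ham_d", "ymrs",
                "cpz_mg", "duration_of_illness_months")
  merged <- merge(slopes, sim$cohort, by = c("participant_id", "group",
                                             "visit"))
  pat <- merged[merged$group == "patient", ]
  correlations <- if (nrow(pat))
    spearman_screen(pat, measures, family_vars = c("group", "visit",
                                                   "region"),
                    method = config$fwe_method, alpha = config$alpha)
  else NULL
  demographics <- demographic_tests(sim$cohort, baseline = cfg$visits[1])
  utils::write.csv(models, file.path(out_dir, "model_results.csv"),
                   row.names = FALSE)
  utils::write.csv(within_group, file.path(out_dir, "within_group_tests.csv"),
                   row.names = FALSE)
  if (!is.null(correlations))
    utils::write.csv(correlations, file.path(out_dir, "correlations.csv"),
                     row.names = FALSE)
  utils::write.csv(demographics, file.path(out_dir, "demographics.csv"),
                   row.names = FALSE)

  summary <- list(
    seed = config$seed,
    window = unclass(window)[c("t_peak_s", "t_return_s", "duration_s",
                               "start_index", "end_index")],
    n_runs_excluded = sum(qc_tab$excluded),
    n_participants = cfg$n_control + cfg$n_patient,
    model_results = models,
    within_group = within_group)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  yaml::write_yaml(config_snapshot(config),
                   file.path(out_dir, "config_snapshot.yaml"))
  log_lines <- c(log_lines,
                 sprintf("elapsed: %.1f s",
                         as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  writeLines(log_lines, file.path(out_dir, "run.log"))

  invisible(list(cohort = sim$cohort, qc = qc_tab, residuals = resid_tab,
                 window = window, slopes = slopes, models = models,
                 within_group = within_group, correlations = correlations,
                 demographics = demographics,
                 ground_truth = sim$ground_truth, summary = summary))
}

# serializable view of a pipeline_config
config_snapshot <- function(config) {
  sim <- unclass(config$sim)
  sim$slope_means <- NULL
  list(sim = sim,
       slope_means = as.list(config$sim$slope_means),
       qc = list(sd_mult = config$qc_sd_mult,
                 motion_mm = config$qc_motion_mm,
                 max_in_window = config$qc_max_in_window),
       window = list(source = config$window_source,
                     t_peak_s = config$fixed_window[1],
                     t_return_s = config$fixed_window[2]),
       stats = list(ddf = config$ddf, fwe_method = config$fwe_method,
                    alpha = config$alpha),
       seed = config$seed)
}

# Table-1-style demographics and clinical comparisons on a simulated cohort
demographic_tests <- function(cohort, baseline = "baseline") {
  base <- cohort[cohort$visit == baseline, ]
  rows <- list()
  cat_test <- function(label, tab) {
    r <- categorical_group_test(tab)
    data.frame(comparison = label, type = "chi-square",
               statistic = r$statistic, df = r$df, p = r$p)
  }
  rows$sex <- cat_test("sex by group", table(base$group, base$sex))
  rows$race <- cat_test("race by group", table(base$group, base$race))
  rows$hand <- cat_test("handedness by group",
                        table(base$group, base$handedness))
  pat <- cohort[cohort$group == "patient", ]
  if (nrow(pat) && !all(is.na(pat$on_antipsychotic)))
    rows$ap <- cat_test("antipsychotic by visit",
                        table(pat$visit, pat$on_antipsychotic))
  for (v in c("age", "education_years", "parental_education_years", "wtar")) {
    a <- stats::anova(stats::lm(base[[v]] ~ base$group))
    rows[[v]] <- data.frame(comparison = paste(v, "by group"), type = "F",
                            statistic = a$`F value`[1], df = a$Df[2],
                            p = a$`Pr(>F)`[1])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Render a human-readable report from a pipeline run directory
#'
#' Formats the within-group habituation table (mean ± SD, t, df, p per
#' group/region/visit) and the region-wise model table (β, SE, F, df, p,
#' d, percent slower), flagging entries significant at the configured
#' alpha. The rendering is a pure function of the run directory.
#'
#' @param run_dir directory written by [run_pipeline()].
#' @param alpha significance flag threshold.
#' @return character vector of report lines (also written to `report.txt`
#'   inside `run_dir`), invisibly.
#' @export
make_report <- function(run_dir, alpha = 0.05) {
  sfile <- file.path(run_dir, "summary.json")
  if (!file.exists(sfile)) stop("no summary.json in ", run_dir,
                                call. = FALSE)
  s <- jsonlite::read_json(sfile, simplifyVector = TRUE)
  if (is.null(s$window) || is.null(s$model_results))
    stop("corrupt summary: missing window or model_results", call. = FALSE)
  star <- function(p) ifelse(is.finite(p) & p <= alpha, "*", "")
  lines <- c(sprintf("Habituation analysis report (seed %s)", s$seed),
             sprintf("Habituation window: %g-%g s (%g s, volumes %d-%d)",
                     s$window$t_peak_s, s$window$t_return_s,
                     s$window$duration_s, s$window$start_index,
                     s$window$end_index),
             sprintf("Runs excluded by QC: %d", s$n_runs_excluded), "",
             "Within-group habituation (one-sided t vs 0):")
  wg <- s$within_group
  for (i in seq_len(NROW(wg)))
    lines <- c(lines,
               sprintf("  %-8s %-9s %-22s %6.2f ± %.2f  t(%d) = %6.2f  p = %.3g%s",
                       wg$group[i], wg$visit[i], wg$region[i], wg$mean[i],
                       wg$sd[i], wg$df[i], wg$t[i], wg$p[i], star(wg$p[i])))
  lines <- c(lines, "", "Mixed-model effects by region:")
  mr <- s$model_results
  for (i in seq_len(NROW(mr))) {
    extra <- if (is.finite(mr$percent_slower[i]))
      sprintf("  (%.0f%% slower)", mr$percent_slower[i]) else ""
    lines <- c(lines,
               sprintf("  %-22s %-10s F(%d,%g) = %6.2f  β = %6.3f  SE = %.3f  d = %5.2f  p = %.3g%s%s",
                       mr$region[i], mr$effect[i], mr$df_num[i],
                       round(mr$df_den[i], 1), mr$F[i], mr$beta[i],
                       mr$se[i], mr$cohen_d[i], mr$p[i], star(mr$p[i]),
                       extra))
  }
  writeLines(lines, file.path(run_dir, "report.txt"))
  invisible(lines)
}
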