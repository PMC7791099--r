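#' ROI time-series container
#'
#' Residual BOLD signal for one participant x region x hemisphere x visit,
#' sampled every `tr_seconds`. Values are in arbitrary residual-signal units
#' with baseline near 0.
#'
#' @param signal numeric vector, one value per volume.
#' @param tr_seconds sampling interval (s).
#' @param participant_id,group,visit,region,hemisphere metadata labels;
#'   `hemisphere` is `"left"`, `"right"` or `"averaged"`.
#' @return An object of class `"roi_timeseries"`.
#' @export
roi_timeseries <- function(signal, tr_seconds, participant_id = NA_character_,
                           group = NA_character_, visit = NA_character_,
                           region = NA_character_, hemisphere = "averaged") {
  stopifnot(is.numeric(signal), all(is.finite(signal)), tr_seconds > 0)
  structure(list(participant_id = participant_id, group = group,
                 visit = visit, region = region, hemisphere = hemisphere,
                 tr_seconds = tr_seconds, signal = as.numeric(signal)),
            class = "roi_timeseries")
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("<roi_timeseries> %s %s %s %s (%s), %d volumes @ TR %gs\n",
              x$participant_id, x$group, x$visit, x$region, x$hemisphere,
              length(x$signal), x$tr_seconds))
  invisible(x)
}

# stationary AR(1) series with marginal sd `sd` and coefficient `phi`
ar1_noise <- function(n, sd, phi) {
  if (sd == 0 || n == 0) return(numeric(n))
  innov <- stats::rnorm(n, 0, sd * sqrt(1 - phi^2))
  as.numeric(stats::filter(innov, phi, method = "recursive",
                           init = stats::rnorm(1, 0, sd)))
}

# truncated-normal draws by inverse-CDF
rtruncnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  stats::qnorm(stats::runif(n, stats::pnorm(lo, mean, sd),
                            stats::pnorm(hi, mean, sd)), mean, sd)
}

#' Build the trial schedule of a repetition run
#'
#' Trials start at 0 and recur every `soa_s` seconds for the whole run. A
#' fraction `target_fraction` of trials carry a small-image target used for
#' the attention task, but never within the first `no_target_window_s`
#' seconds so that the habituation window stays target-free.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed; the schedule is deterministic given it.
#' @return data.frame with columns `trial`, `onset_s`, `is_target`.
#' @export
build_trial_schedule <- function(cfg, seed) {
  validate_sim_config(cfg)
  set.seed(seed)
  onsets <- seq(0, cfg$run_duration_s - cfg$soa_s, by = cfg$soa_s)
  eligible <- onsets >= cfg$no_target_window_s
  is_target <- logical(length(onsets))
  is_target[eligible] <- stats::runif(sum(eligible)) < cfg$target_fraction
  data.frame(trial = seq_along(onsets), onset_s = onsets,
             is_target = is_target)
}

# deterministic mean signal shape: linear rise 0 -> novelty over [0, peak],
# linear decay at rate b' * novelty over [peak, return], exponential
# relaxation back to baseline afterwards
mean_signal_shape <- function(times, novelty, b_prime, peak, ret, tau) {
  end_val <- novelty * (1 + b_prime * (ret - peak))
  out <- numeric(length(times))
  rise <- times <= peak
  out[rise] <- novelty * times[rise] / peak
  dec <- times > peak & times <= ret
  out[dec] <- novelty + b_prime * novelty * (times[dec] - peak)
  late <- times > ret
  out[late] <- end_val * exp(-(times[late] - ret) / tau)
  out
}

#' Simulate one repetition run for a pair of hemispheres
#'
#' The mean signal rises from baseline 0 to the novelty amplitude at
#' `peak_time_s`, declines linearly with raw slope `true_b_prime *
#' true_novelty` (signal units per second) until `return_time_s`, then
#' relaxes exponentially back to baseline. Stationary AR(1) noise is added;
#' the left and right series share a common noise component so their
#' correlation is approximately `hemi_correlation`.
#'
#' @param cfg a [sim_config()].
#' @param true_b_prime true normalized habituation slope (per second).
#' @param true_novelty true novelty amplitude (signal units, > 0).
#' @param seed integer seed.
#' @param participant_id,group,visit,region metadata copied into the output.
#' @param enforce_range if `TRUE`, error when `|true_b_prime| *
#'   (return_time_s - peak_time_s) > 1`, i.e. when the mean decay would carry
#'   the signal further than one novelty amplitude below its peak before the
#'   end of the window. The cohort generator disables this because Gaussian
#'   per-participant slope draws are unbounded.
#' @return list with `left` and `right` [roi_timeseries()] and a `truth`
#'   record of the generating parameters.
#' @export
simulate_roi_run <- function(cfg, true_b_prime, true_novelty, seed,
                             participant_id = NA_character_,
                             group = NA_character_, visit = NA_character_,
                             region = NA_character_, enforce_range = TRUE) {
  validate_sim_config(cfg)
  stopifnot(is.finite(true_b_prime), is.finite(true_novelty),
            true_novelty > 0)
  dur <- cfg$return_time_s - cfg$peak_time_s
  if (enforce_range && abs(true_b_prime) * dur > 1)
    stop(sprintf(paste0("undershoot: |true_b_prime| * window duration = ",
                        "%.3g * %.3g = %.3g exceeds 1; the mean signal would ",
                        "fall below baseline by more than the novelty ",
                        "amplitude (true_novelty = %.3g)"),
                 abs(true_b_prime), dur, abs(true_b_prime) * dur,
                 true_novelty), call. = FALSE)
  set.seed(seed)
  nv <- n_volumes(cfg)
  times <- (seq_len(nv) - 1) * cfg$tr_seconds
  m <- mean_signal_shape(times, true_novelty, true_b_prime,
                         cfg$peak_time_s, cfg$return_time_s,
                         cfg$recovery_tau_s)
  rho <- cfg$hemi_correlation
  common <- ar1_noise(nv, cfg$noise_sd, cfg$ar1_coef)
  eL <- ar1_noise(nv, cfg$noise_sd, cfg$ar1_coef)
  eR <- ar1_noise(nv, cfg$noise_sd, cfg$ar1_coef)
  left  <- m + sqrt(rho) * common + sqrt(1 - rho) * eL
  right <- m + sqrt(rho) * common + sqrt(1 - rho) * eR
  mk <- function(sig, hemi) roi_timeseries(sig, cfg$tr_seconds,
                                           participant_id, group, visit,
                                           region, hemi)
  list(left = mk(left, "left"), right = mk(right, "right"),
       truth = list(true_b_prime = true_b_prime,
                    true_novelty = true_novelty, seed = seed))
}

#' Draw a table of true normalized slopes for a cohort
#'
#' The slope-draw stage of the cohort generator, exposed on its own: per
#' participant x visit x region, the true b' is the configured
#' group/visit/region cell mean plus a stable participant x region component
#' (variance `slope_icc * slope_sd^2`, shared across visits — habituation
#' rate is a stable individual trait) plus a visit-specific deviation
#' (variance `(1 - slope_icc) * slope_sd^2`), so the total cell SD is
#' `slope_sd`. Used directly for statistical-calibration studies where the
#' time-series stage is not under test.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed, or `NULL` to continue the caller's RNG stream
#'   (replicate draws from one stream stay independent; repeated reseeding
#'   does not guarantee that).
#' @return data.frame with `participant_id`, `group`, `visit`, `region`,
#'   `b_prime`.
#' @export
simulate_slope_table <- function(cfg, seed = cfg$seed) {
  validate_sim_config(cfg)
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$n_control + cfg$n_patient
  ids <- sprintf("P%03d", seq_len(n))
  groups <- rep(c("control", "patient"), c(cfg$n_control, cfg$n_patient))
  grid <- expand.grid(participant_id = ids, visit = cfg$visits,
                      region = cfg$regions, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid$group <- groups[match(grid$participant_id, ids)]
  mu <- mapply(slope_mean_for, group = grid$group, visit = grid$visit,
               region = grid$region, MoreArgs = list(cfg = cfg))
  sd_between <- cfg$slope_sd * sqrt(cfg$slope_icc)
  sd_within <- cfg$slope_sd * sqrt(1 - cfg$slope_icc)
  subj_grid <- expand.grid(participant_id = ids, region = cfg$regions,
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  subj_grid$u <- stats::rnorm(nrow(subj_grid), 0, sd_between)
  u <- subj_grid$u[match(paste(grid$participant_id, grid$region),
                         paste(subj_grid$participant_id, subj_grid$region))]
  grid$b_prime <- mu + u + stats::rnorm(nrow(grid), 0, sd_within)
  grid[, c("participant_id", "group", "visit", "region", "b_prime")]
}

# demographic and clinical score draws; values only exercise the
# demographics tables and the correlation screen downstream
draw_demographics <- function(n, group) {
  ctl <- group == "control"
  p_male  <- ifelse(ctl, 0.72, 0.77)
  p_right <- ifelse(ctl, 0.91, 0.94)
  race <- character(n)
  for (i in seq_len(n)) {
    pr <- if (ctl[i]) c(53, 11, 4) / 68 else c(53, 16, 1) / 70
    race[i] <- sample(c("white", "black", "other"), 1, prob = pr)
  }
  data.frame(
    sex = ifelse(stats::runif(n) < p_male, "male", "female"),
    race = race,
    handedness = ifelse(stats::runif(n) < p_right, "right", "left"),
    age = round(rtruncnorm(n, ifelse(ctl, 22, 21), ifelse(ctl, 2.9, 3.8),
                           13, 40)),
    education_years = round(rtruncnorm(n, ifelse(ctl, 15, 13),
                                       ifelse(ctl, 1.9, 2.3), 8, 20)),
    parental_education_years = round(rtruncnorm(n, 15,
                                                ifelse(ctl, 2.4, 2.7), 8, 20)),
    wtar = round(rtruncnorm(n, ifelse(ctl, 112, 103),
                            ifelse(ctl, 10.5, 16), 75, 135)),
    scip = round(rtruncnorm(n, ifelse(ctl, 24, 20), ifelse(ctl, 4, 5), 0, 30))
  )
}

# patient clinical scores for one visit (instrument floors enforced)
draw_clinical <- function(n, visit) {
  b <- visit == "baseline"
  on_ap <- stats::runif(n) < if (b) 0.84 else 0.64
  cpz <- ifelse(on_ap,
                rtruncnorm(n, if (b) 271 else 196, if (b) 181.3 else 219.7,
                           25, Inf), 0)
  data.frame(
    panss_total = round(rtruncnorm(n, if (b) 66 else 51,
                                   if (b) 20.1 else 14.9, 30, 210)),
    panss_positive = round(rtruncnorm(n, if (b) 17 else 13,
                                      if (b) 6.9 else 4.6, 7, 49)),
    panss_negative = round(rtruncnorm(n, if (b) 17 else 12,
                                      if (b) 7.8 else 6.3, 7, 49)),
    panss_general = round(rtruncnorm(n, if (b) 33 else 26,
                                     if (b) 9.1 else 7.0, 16, 112)),
    ham_d = round(rtruncnorm(n, if (b) 9 else 5, if (b) 6.3 else 4.2, 0, 52)),
    ymrs = round(rtruncnorm(n, if (b) 3 else 2, if (b) 4.4 else 2.7, 0, 60)),
    cpz_mg = round(cpz),
    on_antipsychotic = on_ap,
    duration_of_illness_months = round(rtruncnorm(n, 7, 5.7, 1, 24)) +
      if (b) 0 else 24
  )
}

#' Simulate a full longitudinal habituation study
#'
#' Generates a cohort roster with demographics and (for patients) clinical
#' scores, per-run motion traces and global-intensity series with injected
#' spike artifacts, repetition-task ROI time-series for every participant x
#' visit x region x hemisphere, and a ground-truth record of every generating
#' parameter. Fully reproducible from `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return list with elements
#'   \describe{
#'     \item{cohort}{one row per participant x visit: group, demographics,
#'       clinical scores (patients only), `qc_excluded`.}
#'     \item{timeseries}{tidy data.frame: `participant_id`, `group`, `visit`,
#'       `region`, `hemisphere`, `volume` (0-based), `time_s`, `signal`.}
#'     \item{runs}{per participant x visit x volume: global signal and the 6
#'       motion parameters.}
#'     \item{schedules}{trial schedule per participant x visit.}
#'     \item{ground_truth}{list: `slopes` (true b', novelty per cell),
#'       `outliers` (injected spike volumes), `config` (the input).}
#'   }
#' @export
simulate_cohort <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  n <- cfg$n_control + cfg$n_patient
  ids <- sprintf("P%03d", seq_len(n))
  groups <- rep(c("control", "patient"), c(cfg$n_control, cfg$n_patient))
  nv <- n_volumes(cfg)
  times <- (seq_len(nv) - 1) * cfg$tr_seconds

  demo <- draw_demographics(n, groups)
  truth <- simulate_slope_table(cfg, seed = sample.int(2^31 - 1, 1))
  truth$true_novelty <- pmax(rtruncnorm(nrow(truth), cfg$novelty_mean,
                                        cfg$novelty_sd, 0.5, Inf), 0.5)

  # independent sub-seeds for every run, below 2^31
  run_grid <- expand.grid(participant_id = ids, visit = cfg$visits,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  run_grid$seed <- sample.int(2^31 - 1, nrow(run_grid))

  ts_list <- vector("list", nrow(run_grid) * length(cfg$regions))
  runs_list <- vector("list", nrow(run_grid))
  sched_list <- vector("list", nrow(run_grid))
  out_list <- vector("list", nrow(run_grid))
  qc_flag <- logical(nrow(run_grid))
  win_idx <- seq(floor(cfg$peak_time_s / cfg$tr_seconds),
                 floor(cfg$return_time_s / cfg$tr_seconds))  # 0-based

  k <- 0L
  for (r in seq_len(nrow(run_grid))) {
    pid <- run_grid$participant_id[r]; vis <- run_grid$visit[r]
    grp <- groups[match(pid, ids)]
    set.seed(run_grid$seed[r])
    # motion: small mean-zero AR(1) jitter about the reference position
    mot <- matrix(c(ar1_noise(nv, 0.05, 0.8), ar1_noise(nv, 0.05, 0.8),
                    ar1_noise(nv, 0.05, 0.8), ar1_noise(nv, 1e-3, 0.8),
                    ar1_noise(nv, 1e-3, 0.8), ar1_noise(nv, 1e-3, 0.8)),
                  ncol = 6)
    colnames(mot) <- c("trans_x", "trans_y", "trans_z",
                       "rot_x", "rot_y", "rot_z")
    gsig <- 500 + stats::rnorm(nv, 0, 2)
    spikes <- which(stats::runif(nv) < cfg$outlier_rate)
    spike_sign <- sample(c(-1, 1), length(spikes), replace = TRUE)
    if (length(spikes))
      gsig[spikes] <- gsig[spikes] + 50 * spike_sign
    runs_list[[r]] <- data.frame(participant_id = pid, visit = vis,
                                 volume = seq_len(nv) - 1L,
                                 global_signal = gsig, mot)
    out_list[[r]] <- if (length(spikes))
      data.frame(participant_id = pid, visit = vis,
                 volume = spikes - 1L) else NULL
    sched <- build_trial_schedule(cfg, seed = sample.int(2^31 - 1, 1))
    sched_list[[r]] <- cbind(participant_id = pid, visit = vis, sched)

    # QC status from the package's own detection + exclusion rule
    det <- detect_outlier_volumes(gsig, motion_trace(mot))
    qc_flag[r] <- sum(det %in% win_idx) >= 2

    for (reg in cfg$regions) {
      hit <- truth$participant_id == pid & truth$visit == vis &
        truth$region == reg
      run <- simulate_roi_run(cfg, truth$b_prime[hit],
                              truth$true_novelty[hit],
                              seed = sample.int(2^31 - 1, 1),
                              participant_id = pid, group = grp, visit = vis,
                              region = reg, enforce_range = FALSE)
      if (length(spikes)) {
        # the same scanner artifact hits every ROI
        amp <- 10 * cfg$noise_sd * spike_sign
        run$left$signal[spikes] <- run$left$signal[spikes] + amp
        run$right$signal[spikes] <- run$right$signal[spikes] + amp
      }
      k <- k + 1L
      ts_list[[k]] <- data.frame(
        participant_id = pid, group = grp, visit = vis, region = reg,
        hemisphere = rep(c("left", "right"), each = nv),
        volume = rep(seq_len(nv) - 1L, 2), time_s = rep(times, 2),
        signal = c(run$left$signal, run$right$signal))
    }
  }

  cohort <- data.frame(participant_id = rep(ids, length(cfg$visits)),
                       group = rep(groups, length(cfg$visits)),
                       visit = rep(cfg$visits, each = n))
  cohort <- cbind(cohort, demo[rep(seq_len(n), length(cfg$visits)), ])
  clin_cols <- c("panss_total", "panss_positive", "panss_negative",
                 "panss_general", "ham_d", "ymrs", "cpz_mg",
                 "on_antipsychotic", "duration_of_illness_months")
  for (cc in clin_cols) cohort[[cc]] <- NA_real_
  for (vis in cfg$visits) {
    pat <- cohort$visit == vis & cohort$group == "patient"
    if (any(pat)) {
      cl <- draw_clinical(sum(pat), vis)
      for (cc in clin_cols) cohort[[cc]][pat] <- cl[[cc]]
    }
  }
  cohort$on_antipsychotic <- as.logical(cohort$on_antipsychotic)
  key <- paste(cohort$participant_id, cohort$visit)
  cohort$qc_excluded <- qc_flag[match(key, paste(run_grid$participant_id,
                                                 run_grid$visit))]
  rownames(cohort) <- NULL

  names(truth)[names(truth) == "b_prime"] <- "true_b_prime"
  list(cohort = cohort,
       timeseries = do.call(rbind, ts_list),
       runs = do.call(rbind, runs_list),
       schedules = do.call(rbind, sched_list),
       ground_truth = list(slopes = truth,
                           outliers = do.call(rbind, out_list),
                           config = cfg))
}
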