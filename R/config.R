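#' Default per-cell mean normalized habituation slopes
#'
#' Group- and visit-specific mean normalized habituation slopes (b', per
#' second) for the three regions of interest, as used to parameterize the
#' synthetic cohort. Controls habituate in all regions; patients show
#' attenuated (less negative) slopes, with habituation preserved only in the
#' FFA. Values are the study conditions the generator emulates.
#'
#' @return A data.frame with columns `group`, `visit`, `region`, `mean_b_prime`.
#' @export
default_slope_means <- function() {
  regions <- c("anterior_hippocampus", "occipital_pole", "FFA")
  data.frame(
    group  = rep(c("control", "patient"), each = 6),
    visit  = rep(rep(c("baseline", "followup"), each = 3), 2),
    region = rep(regions, 4),
    mean_b_prime = c(
      -0.16, -0.12, -0.48,   # control baseline
      -0.11, -0.09, -0.37,   # control follow-up
      -0.06,  0.06, -0.29,   # patient baseline
       0.00,  0.02, -0.23),  # patient follow-up
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration for a synthetic habituation study
#'
#' Builds and validates the configuration object consumed by the cohort
#' generator. Defaults reproduce the study conditions: 2-min runs of 1 Hz
#' stimulus presentations with 10% small-image targets (none in the first
#' 10 s), a novelty peak 8 s post-onset with linear decay until return to
#' baseline at 18 s, group/visit/region slope means from
#' [default_slope_means()], and AR(1) volume noise.
#'
#' @param n_control,n_patient group sizes.
#' @param visits visit labels; first is the baseline visit.
#' @param regions region labels.
#' @param tr_seconds sampling interval (s).
#' @param run_duration_s run length (s).
#' @param soa_s stimulus onset asynchrony (s).
#' @param target_fraction proportion of trials that are small-image targets.
#' @param no_target_window_s no targets before this time (s).
#' @param peak_time_s novelty-peak latency (s).
#' @param return_time_s return-to-baseline latency (s).
#' @param slope_means data.frame (group, visit, region, mean_b_prime) of true
#'   mean normalized slopes, per second.
#' @param slope_sd total SD of true b' within a group/visit/region cell.
#' @param slope_icc fraction of `slope_sd^2` attributable to a stable
#'   participant-level component shared across visits (within-person
#'   stability of habituation rate); the remainder is visit-specific.
#' @param novelty_mean,novelty_sd novelty-amplitude distribution
#'   (residual-signal units).
#' @param noise_sd marginal SD of the AR(1) volume noise.
#' @param ar1_coef temporal autocorrelation of the noise, |ar1_coef| < 1.
#' @param hemi_correlation target correlation of left/right noise, in (0, 1].
#' @param outlier_rate per-volume probability of an injected global-intensity
#'   spike.
#' @param recovery_tau_s time constant (s) of the post-window relaxation of
#'   the mean signal back to baseline.
#' @param seed integer seed; every simulated quantity is reproducible from it.
#'
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_control = 68, n_patient = 70,
                       visits = c("baseline", "followup"),
                       regions = c("anterior_hippocampus", "occipital_pole", "FFA"),
                       tr_seconds = 2.0, run_duration_s = 120, soa_s = 1.0,
                       target_fraction = 0.10, no_target_window_s = 10,
                       peak_time_s = 8, return_time_s = 18,
                       slope_means = default_slope_means(), slope_sd = 0.3,
                       slope_icc = 0.5,
                       novelty_mean = 10, novelty_sd = 2,
                       noise_sd = 1, ar1_coef = 0.3, hemi_correlation = 0.8,
                       outlier_rate = 0.005, recovery_tau_s = 4, seed = 1L) {
  cfg <- list(
    n_control = n_control, n_patient = n_patient, visits = visits,
    regions = regions, tr_seconds = tr_seconds,
    run_duration_s = run_duration_s, soa_s = soa_s,
    target_fraction = target_fraction,
    no_target_window_s = no_target_window_s,
    peak_time_s = peak_time_s, return_time_s = return_time_s,
    slope_means = slope_means, slope_sd = slope_sd, slope_icc = slope_icc,
    novelty_mean = novelty_mean, novelty_sd = novelty_sd,
    noise_sd = noise_sd, ar1_coef = ar1_coef,
    hemi_correlation = hemi_correlation, outlier_rate = outlier_rate,
    recovery_tau_s = recovery_tau_s, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param cfg a `sim_config` object.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  fail <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) fail <<- c(fail, msg)
  chk(cfg$n_control >= 0 && cfg$n_patient >= 0 &&
        cfg$n_control + cfg$n_patient > 0,
      "group sizes must be non-negative with at least one participant")
  chk(length(cfg$visits) >= 1 && !anyDuplicated(cfg$visits),
      "visits must be distinct labels")
  chk(length(cfg$regions) >= 1, "at least one region is required")
  chk(cfg$tr_seconds > 0, "tr_seconds must be positive")
  chk(cfg$run_duration_s > 0, "run_duration_s must be positive")
  chk(cfg$soa_s > 0, "soa_s must be positive")
  chk(cfg$target_fraction >= 0 && cfg$target_fraction < 1,
      "target_fraction must be in [0, 1)")
  chk(cfg$peak_time_s > 0 && cfg$peak_time_s < cfg$return_time_s &&
        cfg$return_time_s <= cfg$run_duration_s,
      "require 0 < peak_time_s < return_time_s <= run_duration_s")
  chk(cfg$slope_sd >= 0 && cfg$noise_sd >= 0 && cfg$novelty_sd >= 0,
      "slope_sd, noise_sd, novelty_sd must be >= 0")
  chk(cfg$slope_icc >= 0 && cfg$slope_icc <= 1,
      "slope_icc must be in [0, 1]")
  chk(abs(cfg$ar1_coef) < 1, "|ar1_coef| must be < 1")
  chk(cfg$hemi_correlation > 0 && cfg$hemi_correlation <= 1,
      "hemi_correlation must be in (0, 1]")
  chk(cfg$outlier_rate >= 0 && cfg$outlier_rate < 1,
      "outlier_rate must be in [0, 1)")
  chk(is.data.frame(cfg$slope_means) &&
        all(c("group", "visit", "region", "mean_b_prime") %in%
              names(cfg$slope_means)),
      "slope_means must have columns group, visit, region, mean_b_prime")
  if (length(fail)) stop("invalid sim_config: ", paste(fail, collapse = "; "),
                         call. = FALSE)
  cfg
}

# volume count of one run
n_volumes <- function(cfg) as.integer(floor(cfg$run_duration_s / cfg$tr_seconds))

# look up the configured true mean slope for one cell
slope_mean_for <- function(cfg, group, visit, region) {
  sm <- cfg$slope_means
  hit <- sm$group == group & sm$visit == visit & sm$region == region
  if (sum(hit) != 1L)
    stop("slope_means has no unique entry for (", group, ", ", visit, ", ",
         region, ")", call. = FALSE)
  sm$mean_b_prime[hit]
}
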