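#' Habituation window
#'
#' The analysis interval from the novelty peak to the return to baseline,
#' expressed both in stimulus-onset-relative seconds and in 0-based volume
#' indices at the sampling interval `tr_seconds`.
#'
#' @param t_peak_s window start (s after first stimulus onset).
#' @param t_return_s window end (s).
#' @param tr_seconds sampling interval (s).
#' @return An object of class `"habituation_window"` with fields
#'   `t_peak_s`, `t_return_s`, `start_index`, `end_index` (0-based volumes),
#'   `duration_s`, `tr_seconds`.
#' @export
habituation_window <- function(t_peak_s, t_return_s, tr_seconds) {
  stopifnot(tr_seconds > 0)
  if (!(t_peak_s > 0 && t_return_s > t_peak_s))
    stop("require 0 < t_peak_s < t_return_s (got ", t_peak_s, ", ",
         t_return_s, ")", call. = FALSE)
  structure(list(t_peak_s = t_peak_s, t_return_s = t_return_s,
                 start_index = as.integer(floor(t_peak_s / tr_seconds)),
                 end_index = as.integer(floor(t_return_s / tr_seconds)),
                 duration_s = t_return_s - t_peak_s,
                 tr_seconds = tr_seconds),
            class = "habituation_window")
}

#' @export
print.habituation_window <- function(x, ...) {
  cat(sprintf("<habituation_window> [%g s, %g s] (%g s), volumes %d..%d @ TR %gs\n",
              x$t_peak_s, x$t_return_s, x$duration_s, x$start_index,
              x$end_index, x$tr_seconds))
  invisible(x)
}

#' Detect the habituation window from the control-group mean series
#'
#' The window is defined on the baseline-visit control group: its start is
#' the time of peak signal after stimulus onset (the novelty response;
#' earliest time on ties) and its end is the first post-peak time at which
#' the signal has returned to baseline — at or below `baseline_tol_frac`
#' times the peak amplitude, baseline being 0 for residual series. The
#' window must not contain any small-image target onset.
#'
#' @param control_mean group-average residual series, time-locked to the
#'   first stimulus onset (volume 0 at onset).
#' @param tr_seconds sampling interval (s).
#' @param target_onsets onset times (s) of small-image targets, used to
#'   verify the window is target-free.
#' @param baseline_tol_frac return-to-baseline tolerance as a fraction of
#'   the peak amplitude; an exact zero-crossing is noise-fragile.
#' @param max_return_s optional cap (s): error if no return is found by then
#'   (defaults to the end of the series).
#' @return A [habituation_window()].
#' @export
detect_window <- function(control_mean, tr_seconds, target_onsets = numeric(0),
                          baseline_tol_frac = 0.05, max_return_s = NULL) {
  stopifnot(is.numeric(control_mean), all(is.finite(control_mean)),
            tr_seconds > 0)
  n <- length(control_mean)
  if ((n - 1) * tr_seconds < 20)
    stop("series must cover at least 20 s post-onset", call. = FALSE)
  times <- (seq_len(n) - 1) * tr_seconds
  ipeak <- which.max(control_mean)  # earliest on ties
  if (ipeak == 1L)
    stop("signal peaks at stimulus onset (t = 0): no novelty rise to define ",
         "a window start", call. = FALSE)
  if (ipeak == n)
    stop("signal peaks at the final volume: no decay segment to analyze",
         call. = FALSE)
  peak_val <- control_mean[ipeak]
  tol <- baseline_tol_frac * abs(peak_val)
  post <- seq(ipeak + 1L, n)
  cap <- if (is.null(max_return_s)) times[n] else max_return_s
  post <- post[times[post] <= cap]
  iret <- post[control_mean[post] <= tol]
  if (!length(iret))
    stop("signal does not return to baseline within ", cap,
         " s post-onset; consider raising max_return_s or the tolerance",
         call. = FALSE)
  iret <- iret[1]
  win <- habituation_window(times[ipeak], times[iret], tr_seconds)
  inside <- target_onsets >= win$t_peak_s & target_onsets <= win$t_return_s
  if (any(inside))
    stop("habituation window [", win$t_peak_s, ", ", win$t_return_s,
         "] s contains target onsets at ",
         paste(target_onsets[inside], collapse = ", "), " s", call. = FALSE)
  win
}

#' Novelty-response amplitude
#'
#' The fMRI signal amplitude at the beginning of the habituation window —
#' by default the single volume at the window start, optionally a short
#' average of `width` volumes from the start.
#'
#' @param series a [roi_timeseries()] or numeric vector.
#' @param window a [habituation_window()].
#' @param width number of volumes to average from the window start.
#' @return numeric amplitude (signal units).
#' @export
novelty_amplitude <- function(series, window, width = 1L) {
  sig <- if (inherits(series, "roi_timeseries")) series$signal else series
  stopifnot(inherits(window, "habituation_window"), width >= 1)
  i0 <- window$start_index + 1L  # to 1-based
  if (i0 + width - 1L > length(sig))
    stop("window start beyond end of series", call. = FALSE)
  mean(sig[i0:(i0 + width - 1L)])
}

#' Normalized habituation slope for one series
#'
#' Fits an ordinary least-squares line to the residual signal over the
#' habituation window (time axis in seconds, so the slope is TR-independent)
#' and normalizes by the novelty amplitude: `b_prime = raw_slope_b /
#' novelty_a`. More negative b' means faster habituation. When the novelty
#' amplitude is too small for stable division (`|novelty_a| <
#' novelty_guard_frac * sd(signal)`), `b_prime` is set to `NA` and flagged,
#' but the raw (unnormalized) slope is always returned.
#'
#' @param series a [roi_timeseries()] or numeric vector.
#' @param window a [habituation_window()].
#' @param tr_seconds sampling interval; taken from `series` when it is a
#'   [roi_timeseries()].
#' @param novelty_width volumes averaged for the novelty amplitude.
#' @param novelty_guard_frac instability guard as a fraction of the run SD.
#' @return list of class `"habituation_result"`: `participant_id`, `region`,
#'   `visit`, `novelty_a`, `raw_slope_b` (units/s), `b_prime` (per s),
#'   `n_window_volumes`, `unreliable` flag.
#' @export
habituation_slope <- function(series, window, tr_seconds = NULL,
                              novelty_width = 1L, novelty_guard_frac = 0.05) {
  meta <- list(participant_id = NA_character_, region = NA_character_,
               visit = NA_character_)
  if (inherits(series, "roi_timeseries")) {
    tr_seconds <- series$tr_seconds
    meta <- series[c("participant_id", "region", "visit")]
    sig <- series$signal
  } else sig <- series
  if (is.null(tr_seconds)) stop("tr_seconds required for a bare vector",
                                call. = FALSE)
  stopifnot(inherits(window, "habituation_window"))
  if (!all(is.finite(sig))) stop("non-finite signal", call. = FALSE)
  idx <- (window$start_index:window$end_index) + 1L  # 1-based
  if (max(idx) > length(sig))
    stop("window extends beyond the series (", length(sig), " volumes)",
         call. = FALSE)
  if (length(idx) < 3)
    stop("habituation window has ", length(idx),
         " volumes; at least 3 are required for a slope", call. = FALSE)
  y <- sig[idx]
  t <- (idx - 1) * tr_seconds
  raw <- sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
  a <- novelty_amplitude(sig, window, width = novelty_width)
  guard <- novelty_guard_frac * stats::sd(sig)
  unreliable <- is.finite(guard) && abs(a) < guard
  structure(list(participant_id = meta$participant_id, region = meta$region,
                 visit = meta$visit, novelty_a = a, raw_slope_b = raw,
                 b_prime = if (unreliable) NA_real_ else
                   if (a == 0 && raw == 0) 0 else raw / a,
                 n_window_volumes = length(idx), unreliable = unreliable),
            class = "habituation_result")
}

#' @export
print.habituation_result <- function(x, ...) {
  cat(sprintf("<habituation_result> %s %s %s: a = %.3g, b = %.3g/s, b' = %.3g/s%s\n",
              x$participant_id, x$region, x$visit, x$novelty_a,
              x$raw_slope_b, x$b_prime,
              if (x$unreliable) " [unreliable: novelty near zero]" else ""))
  invisible(x)
}

#' Re-express a group slope difference as percent slower habituation
#'
#' The group fixed effect from the mixed model is a difference in normalized
#' slope (per second); multiplying by 100 expresses it in percentage points
#' of signal change per second relative to the novelty response.
#'
#' @param beta_group group difference in b' (patient minus control).
#' @return percentage (e.g. 0.11 -> 11).
#' @export
percent_slower <- function(beta_group) {
  stopifnot(is.finite(beta_group))
  100 * beta_group
}

#' Habituation slopes for a tidy time-series table
#'
#' Applies [habituation_slope()] to every participant x region x visit cell
#' of a tidy residual time-series table (hemisphere already averaged).
#'
#' @param ts data.frame with columns `participant_id`, `group`, `visit`,
#'   `region`, `volume`, `signal` (one hemisphere-averaged row per volume).
#' @param window a [habituation_window()].
#' @param tr_seconds sampling interval (s).
#' @inheritParams habituation_slope
#' @return data.frame, one row per cell: `participant_id`, `group`, `visit`,
#'   `region`, `novelty_a`, `raw_slope_b`, `b_prime`, `unreliable`.
#' @export
compute_slopes <- function(ts, window, tr_seconds,
                           novelty_width = 1L, novelty_guard_frac = 0.05) {
  need <- c("participant_id", "group", "visit", "region", "volume", "signal")
  if (!all(need %in% names(ts)))
    stop("time-series table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  cells <- unique(ts[, c("participant_id", "group", "visit", "region")])
  rownames(cells) <- NULL
  res <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    sel <- ts$participant_id == cells$participant_id[i] &
      ts$visit == cells$visit[i] & ts$region == cells$region[i]
    sub <- ts[sel, ]
    sig <- sub$signal[order(sub$volume)]
    h <- habituation_slope(sig, window, tr_seconds = tr_seconds,
                           novelty_width = novelty_width,
                           novelty_guard_frac = novelty_guard_frac)
    res[[i]] <- data.frame(novelty_a = h$novelty_a,
                           raw_slope_b = h$raw_slope_b, b_prime = h$b_prime,
                           unreliable = h$unreliable)
  }
  cbind(cells, do.call(rbind, res))
}
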