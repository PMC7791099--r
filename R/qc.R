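#' Motion trace container
#'
#' Per-volume rigid-body motion estimates: three translations (mm) and three
#' rotations (radians), plus the derived frame-to-frame relative displacement.
#'
#' @param params numeric matrix or data.frame with 6 columns, one row per
#'   volume: translations x/y/z in mm, then rotations x/y/z in radians.
#' @param head_radius_mm radius (mm) used to convert rotation deltas to arc
#'   length on the scalp; 65 mm is the conventional adult default.
#' @return An object of class `"motion_trace"`: list with `params` (matrix)
#'   and `rel_displacement` (mm per volume, first element 0).
#' @export
motion_trace <- function(params, head_radius_mm = 65) {
  params <- as.matrix(params)
  if (ncol(params) != 6)
    stop("motion parameters must have 6 columns (3 translations mm, ",
         "3 rotations rad)", call. = FALSE)
  stopifnot(nrow(params) >= 1, all(is.finite(params)), head_radius_mm > 0)
  structure(list(params = params,
                 rel_displacement = relative_displacement(params,
                                                          head_radius_mm),
                 head_radius_mm = head_radius_mm),
            class = "motion_trace")
}

#' Frame-to-frame relative displacement
#'
#' Composite head-motion magnitude between consecutive volumes: the Euclidean
#' norm of the translation deltas plus the arc length of the rotation deltas
#' at `head_radius_mm`. The first volume has displacement 0 by definition.
#'
#' @param params 6-column motion matrix (translations mm, rotations rad).
#' @param head_radius_mm rotation-to-arc-length radius (mm).
#' @return numeric vector of per-volume displacements (mm), all `>= 0`.
#' @export
relative_displacement <- function(params, head_radius_mm = 65) {
  params <- as.matrix(params)
  if (ncol(params) != 6)
    stop("motion parameters must have 6 columns", call. = FALSE)
  n <- nrow(params)
  if (n == 0) stop("empty motion trace", call. = FALSE)
  if (n == 1) return(0)
  d <- diff(params)
  trans <- sqrt(rowSums(d[, 1:3, drop = FALSE]^2))
  rot <- head_radius_mm * sqrt(rowSums(d[, 4:6, drop = FALSE]^2))
  c(0, trans + rot)
}

#' Detect outlier volumes from global signal and motion
#'
#' A volume is flagged when its volume-to-volume global-intensity change
#' deviates from the mean change by more than `sd_mult` standard deviations
#' of the changes, or when motion at that volume exceeds `motion_mm` — in
#' absolute translation on any axis or in relative displacement. This is the
#' ART artifact-detection convention with a 5 SD / 3 mm default.
#'
#' @param global_signal per-volume mean in-mask intensity.
#' @param motion a [motion_trace()] (or 6-column matrix, converted).
#' @param sd_mult intensity-change threshold in SD units.
#' @param motion_mm motion threshold (mm).
#' @return sorted integer vector of 0-based outlier volume indices.
#' @export
detect_outlier_volumes <- function(global_signal, motion, sd_mult = 5,
                                   motion_mm = 3) {
  if (!inherits(motion, "motion_trace")) motion <- motion_trace(motion)
  n <- length(global_signal)
  if (n < 3) stop("need at least 3 volumes", call. = FALSE)
  if (nrow(motion$params) != n)
    stop("global signal has ", n, " volumes but motion trace has ",
         nrow(motion$params), call. = FALSE)
  stopifnot(all(is.finite(global_signal)), sd_mult > 0, motion_mm > 0)
  ch <- diff(global_signal)
  s <- stats::sd(ch)
  flag_int <- if (s > 0) c(FALSE, abs(ch - mean(ch)) > sd_mult * s)
              else rep(FALSE, n)
  flag_mot <- apply(abs(motion$params[, 1:3, drop = FALSE]) > motion_mm, 1,
                    any) | motion$rel_displacement > motion_mm
  sort(which(flag_int | flag_mot) - 1L)
}

#' Apply the run-level exclusion rule
#'
#' A run is excluded when at least `max_in_window` outlier volumes fall
#' inside the habituation window; outliers elsewhere in the run never
#' trigger exclusion.
#'
#' @param outliers 0-based outlier volume indices (from
#'   [detect_outlier_volumes()]).
#' @param window a [habituation_window()].
#' @param n_volumes run length, for index validation.
#' @param max_in_window exclusion threshold (count, default 2).
#' @return list of class `"qc_report"`: `outlier_volume_indices`,
#'   `n_outliers_in_window`, `excluded`, `reasons`.
#' @export
apply_exclusion_rule <- function(outliers, window, n_volumes = NULL,
                                 max_in_window = 2) {
  outliers <- sort(unique(as.integer(outliers)))
  stopifnot(inherits(window, "habituation_window"))
  if (!is.null(n_volumes) &&
      length(outliers) && any(outliers < 0 | outliers >= n_volumes))
    stop("outlier indices out of range for run of ", n_volumes, " volumes",
         call. = FALSE)
  in_win <- outliers >= window$start_index & outliers <= window$end_index
  n_in <- sum(in_win)
  excluded <- n_in >= max_in_window
  reasons <- character(0)
  if (excluded)
    reasons <- sprintf("%d outlier volumes within the %gs habituation window (threshold %d)",
                       n_in, window$duration_s, max_in_window)
  structure(list(outlier_volume_indices = outliers,
                 n_outliers_in_window = n_in, excluded = excluded,
                 reasons = reasons),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d outliers (%d in window) — %s\n",
              length(x$outlier_volume_indices), x$n_outliers_in_window,
              if (x$excluded) "EXCLUDED" else "retained"))
  if (length(x$reasons)) cat(" ", paste(x$reasons, collapse = "; "), "\n")
  invisible(x)
}
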