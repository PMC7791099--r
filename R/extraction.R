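#' Nuisance design matrix for first-level residualization
#'
#' Assembles the regressors of no interest used to residualize the ROI
#' signal: intercept, 6 motion parameters, relative displacement, one-hot
#' spike columns for flagged outlier volumes, and a boxcar for small-image
#' target presentations. No temporal filter columns are included — slow
#' signal change is the quantity of interest.
#'
#' @param motion a [motion_trace()] or 6-column matrix.
#' @param outliers 0-based outlier volume indices (one spike column each).
#' @param target_onsets target onset times (s).
#' @param n_volumes run length.
#' @param tr_seconds sampling interval (s).
#' @return numeric matrix with `n_volumes` rows and named columns.
#' @export
build_nuisance_design <- function(motion, outliers = integer(0),
                                  target_onsets = numeric(0),
                                  n_volumes, tr_seconds) {
  if (!inherits(motion, "motion_trace")) motion <- motion_trace(motion)
  if (nrow(motion$params) != n_volumes)
    stop("motion trace has ", nrow(motion$params), " rows, expected ",
         n_volumes, call. = FALSE)
  X <- cbind(intercept = rep(1, n_volumes), motion$params,
             rel_disp = motion$rel_displacement)
  for (o in sort(unique(as.integer(outliers)))) {
    if (o < 0 || o >= n_volumes)
      stop("outlier index ", o, " out of range", call. = FALSE)
    col <- numeric(n_volumes); col[o + 1L] <- 1
    X <- cbind(X, col)
    colnames(X)[ncol(X)] <- paste0("outlier_", o)
  }
  if (length(target_onsets)) {
    tv <- floor(target_onsets / tr_seconds)
    tv <- tv[tv >= 0 & tv < n_volumes]
    box <- numeric(n_volumes); box[tv + 1L] <- 1
    X <- cbind(X, targets = box)
  }
  X
}

#' Least-squares residualization against a nuisance design
#'
#' Returns the ordinary-least-squares residual of the signal on the design
#' matrix (intercept included by the caller, conventionally via
#' [build_nuisance_design()]). No temporal filtering is applied. Columns
#' that are identically zero are dropped before fitting; if the remaining
#' design is rank deficient, the collinear columns are named in the error.
#'
#' @param signal per-volume series.
#' @param design numeric matrix, rows = volumes.
#' @return numeric residual series, orthogonal to every retained design
#'   column.
#' @export
residualize <- function(signal, design) {
  design <- as.matrix(design)
  stopifnot(is.numeric(signal), all(is.finite(signal)))
  if (nrow(design) != length(signal))
    stop("design has ", nrow(design), " rows but signal has ",
         length(signal), " volumes", call. = FALSE)
  keep <- colSums(design != 0) > 0
  X <- design[, keep, drop = FALSE]
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, ncol(X))]]
    stop("nuisance design is rank deficient; collinear columns: ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  as.numeric(qr.resid(qrX, signal))
}

#' Mean time-series inside a region-of-interest mask
#'
#' @param image_4d 4-D numeric array (x, y, z, t) or a NIfTI image as read
#'   by `RNifti::readNifti()`.
#' @param mask 3-D binary array or NIfTI mask on the same grid.
#' @return numeric vector: per-volume mean over in-mask voxels.
#' @export
extract_roi_timeseries <- function(image_4d, mask) {
  img <- unclass(as.array(image_4d))
  msk <- unclass(as.array(mask))
  if (length(dim(img)) != 4)
    stop("image must be 4-D (x, y, z, t)", call. = FALSE)
  if (!identical(dim(img)[1:3], dim(msk)[1:3]))
    stop("mask grid ", paste(dim(msk), collapse = "x"),
         " does not match image grid ",
         paste(dim(img)[1:3], collapse = "x"), call. = FALSE)
  sel <- msk != 0
  m <- sum(sel)
  if (m == 0) stop("empty mask", call. = FALSE)
  nt <- dim(img)[4]
  flat <- matrix(img, ncol = nt)
  colMeans(flat[as.vector(sel), , drop = FALSE])
}

#' Write a small synthetic 4-D NIfTI fixture around an ROI series pair
#'
#' Embeds the left/right ROI series into a small volumetric grid: every
#' voxel inside each hemisphere mask carries that hemisphere's series plus
#' independent voxel noise. Used to exercise volumetric extraction without
#' any real imaging data; outputs are standard NIfTI files.
#'
#' @param roi_pair list with `left` and `right` [roi_timeseries()].
#' @param dim_xyz 3-vector grid size.
#' @param left_voxels,right_voxels matrices of voxel coordinates (rows =
#'   voxels, columns = x,y,z), non-overlapping, non-empty.
#' @param voxel_noise_sd SD of independent voxel noise.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return named list of written paths: `image`, `mask_left`, `mask_right`.
#' @export
write_nifti_fixture <- function(roi_pair, dim_xyz = c(8, 8, 4),
                                left_voxels = NULL, right_voxels = NULL,
                                voxel_noise_sd = 0, dir = tempdir(),
                                prefix = "fixture") {
  stopifnot(inherits(roi_pair$left, "roi_timeseries"),
            inherits(roi_pair$right, "roi_timeseries"))
  nt <- length(roi_pair$left$signal)
  stopifnot(length(roi_pair$right$signal) == nt)
  if (is.null(left_voxels))
    left_voxels <- cbind(2:3, 2, 2)
  if (is.null(right_voxels))
    right_voxels <- cbind(2:3, dim_xyz[2] - 1, 2)
  left_voxels <- as.matrix(left_voxels); right_voxels <- as.matrix(right_voxels)
  if (nrow(left_voxels) == 0 || nrow(right_voxels) == 0)
    stop("empty mask", call. = FALSE)
  lin <- function(v) v[, 1] + dim_xyz[1] * (v[, 2] - 1) +
    dim_xyz[1] * dim_xyz[2] * (v[, 3] - 1)
  if (length(intersect(lin(left_voxels), lin(right_voxels))))
    stop("left and right masks overlap", call. = FALSE)
  img <- array(0, c(dim_xyz, nt))
  mskL <- array(0L, dim_xyz); mskR <- array(0L, dim_xyz)
  fill <- function(vox, sig) {
    for (i in seq_len(nrow(vox))) {
      noise <- if (voxel_noise_sd > 0) stats::rnorm(nt, 0, voxel_noise_sd)
               else 0
      img[vox[i, 1], vox[i, 2], vox[i, 3], ] <<- sig + noise
    }
  }
  fill(left_voxels, roi_pair$left$signal)
  fill(right_voxels, roi_pair$right$signal)
  mskL[left_voxels] <- 1L
  mskR[right_voxels] <- 1L
  paths <- list(image = file.path(dir, paste0(prefix, "_bold.nii.gz")),
                mask_left = file.path(dir, paste0(prefix, "_mask_L.nii.gz")),
                mask_right = file.path(dir, paste0(prefix, "_mask_R.nii.gz")))
  RNifti::writeNifti(RNifti::asNifti(img), paths$image)
  RNifti::writeNifti(RNifti::asNifti(mskL), paths$mask_left)
  RNifti::writeNifti(RNifti::asNifti(mskR), paths$mask_right)
  paths
}

#' Average left and right hemisphere series
#'
#' Elementwise mean of the two hemispheres, with the Pearson correlation of
#' the inputs reported as a diagnostic; a warning (not an error) is emitted
#' when the correlation falls below `warn_below`, since averaging weakly
#' correlated series discards signal.
#'
#' @param left,right [roi_timeseries()] for the same participant, region,
#'   visit, of equal length.
#' @param warn_below correlation warning threshold.
#' @return list: `series` (an averaged [roi_timeseries()]) and `correlation`.
#' @export
average_hemispheres <- function(left, right, warn_below = 0.5) {
  stopifnot(inherits(left, "roi_timeseries"),
            inherits(right, "roi_timeseries"))
  for (f in c("participant_id", "region", "visit")) {
    same <- identical(left[[f]], right[[f]]) ||
      (is.na(left[[f]]) && is.na(right[[f]]))
    if (!same)
      stop("hemisphere metadata mismatch on ", f, ": ", left[[f]], " vs ",
           right[[f]], call. = FALSE)
  }
  if (length(left$signal) != length(right$signal))
    stop("hemisphere series lengths differ", call. = FALSE)
  if (left$tr_seconds != right$tr_seconds)
    stop("hemisphere TRs differ", call. = FALSE)
  r <- if (stats::sd(left$signal) == 0 || stats::sd(right$signal) == 0)
    NA_real_ else stats::cor(left$signal, right$signal)
  if (is.finite(r) && r < warn_below)
    warning(sprintf("left/right correlation %.2f below %.2f for %s %s %s",
                    r, warn_below, left$participant_id, left$region,
                    left$visit), call. = FALSE)
  avg <- roi_timeseries((left$signal + right$signal) / 2, left$tr_seconds,
                        left$participant_id, left$group, left$visit,
                        left$region, hemisphere = "averaged")
  list(series = avg, correlation = r)
}

#' Hemisphere-average a tidy time-series table
#'
#' Convenience wrapper: elementwise mean of left and right rows per
#' participant x visit x region x volume, for tables as emitted by
#' [simulate_cohort()]. For per-pair correlation diagnostics use
#' [average_hemispheres()].
#'
#' @param ts tidy data.frame with `participant_id`, `group`, `visit`,
#'   `region`, `hemisphere`, `volume`, `time_s`, `signal`.
#' @return the same table with hemispheres collapsed
#'   (`hemisphere = "averaged"`).
#' @export
hemi_average_table <- function(ts) {
  agg <- stats::aggregate(
    signal ~ participant_id + group + visit + region + volume + time_s,
    data = ts, FUN = mean)
  agg$hemisphere <- "averaged"
  agg[order(agg$participant_id, agg$visit, agg$region, agg$volume), ]
}
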