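# Thermal dosimetry (CEM43), lesion-mask overlap, hottest-voxel / ROI curves,
# and the background precision/accuracy measures used to evaluate
# reconstructions.

#' Cumulative equivalent minutes at 43 degC (CEM43)
#'
#' Sapareto-Dean dose accumulated with each frame's temperature held constant
#' over its interval (rectangle rule, matching the discrete MRTI sampling):
#' per voxel `CEM43 = sum_frames dt_min * Rc^(43 - T_abs)` with
#' `T_abs = baseline + dT`, `Rc = 0.5` for `T_abs >= 43` and `0.25` below.
#'
#' @param series [temperature_series()] of temperature *changes* (degC)
#' @param baseline_temp_c absolute pre-heating temperature (degC, default 37)
#' @return object of class `dose_map` with field `cem43` (equivalent minutes)
#' @export
cem43 <- function(series, baseline_temp_c = 37) {
  if (!inherits(series, "temperature_series"))
    stop("series must be a temperature_series")
  check_scalar(baseline_temp_c, "baseline_temp_c")
  dt_min <- series$frame_interval_s / 60
  nt <- n_frames(series)
  dims <- dim(series$frames)
  dims <- dims[-length(dims)]
  dose <- array(0, dim = dims)
  for (i in seq_len(nt)) {
    t_abs <- baseline_temp_c + get_frame(series, i)
    rc <- ifelse(t_abs >= 43, 0.5, 0.25)
    dose <- dose + dt_min * rc^(43 - t_abs)
  }
  structure(list(cem43 = dose, spacing_mm = series$spacing_mm,
                 baseline_temp_c = baseline_temp_c),
            class = "dose_map")
}

#' Threshold a dose map into an ablation mask
#'
#' @param dose [cem43()] result
#' @param threshold_min dose threshold in equivalent minutes (default 240,
#'   the standard ablation criterion); voxels with `cem43 >= threshold` are
#'   TRUE (boundary included)
#' @return logical array
#' @export
dose_mask <- function(dose, threshold_min = 240) {
  if (!inherits(dose, "dose_map")) stop("dose must be a dose_map")
  check_scalar(threshold_min, "threshold_min", positive = TRUE)
  dose$cem43 >= threshold_min
}

#' Dice similarity coefficient of two masks
#'
#' `2|A & B| / (|A| + |B|)`. Two empty masks agree perfectly by convention
#' (returns 1 with attribute `both_empty = TRUE` as a diagnostic flag).
#'
#' @param a,b logical arrays on the same grid
#' @return scalar in [0, 1]
#' @export
dice <- function(a, b) {
  a <- as_spatial_array(a); b <- as_spatial_array(b)
  if (!same_dims(a, b)) stop("masks must be on the same grid")
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0)
    return(structure(1, both_empty = TRUE))
  2 * sum(a & b) / (na + nb)
}

# In-plane 3x3 block mean about a voxel; for 3D data the block is taken on the
# hottest voxel's slice (third index fixed). Blocks at the grid edge are
# clamped with a warning.
roi_block_mean <- function(frame, center, half_width) {
  dims <- dim(frame)
  nd <- length(dims)
  n_inplane <- min(nd, 2L)
  lo <- hi <- center
  for (ax in seq_len(n_inplane)) {
    lo[ax] <- center[ax] - half_width
    hi[ax] <- center[ax] + half_width
  }
  if (any(lo < 1L) || any(hi > dims)) {
    warning("ROI exceeds the grid; clamped")
    lo <- pmax(lo, 1L); hi <- pmin(hi, dims)
  }
  idx <- lapply(seq_len(nd), function(ax) lo[ax]:hi[ax])
  mean(do.call(`[`, c(list(frame), idx, list(drop = FALSE))))
}

#' Hottest-voxel (or hottest-ROI) temperature curve
#'
#' Per frame, either the maximum voxel (`roi_half_width = 0`) or the mean of
#' the in-plane `(2h+1) x (2h+1)` block centered on the hottest voxel
#' (`roi_half_width = 1` gives the 3x3 ROI used clinically). For 3D data the
#' block is taken in-plane on the hottest voxel's slice.
#'
#' @param series [temperature_series()]
#' @param roi_half_width 0 (single voxel) or 1 (3x3 ROI)
#' @param fixed_location if TRUE, the hottest voxel is located once at the
#'   globally hottest frame and reused for all frames; default is per-frame
#'   re-finding
#' @return numeric vector, one value per frame (degC)
#' @export
hottest_curve <- function(series, roi_half_width = 0L, fixed_location = FALSE) {
  if (!inherits(series, "temperature_series"))
    stop("series must be a temperature_series")
  if (!roi_half_width %in% c(0L, 1L))
    stop("roi_half_width must be 0 (single voxel) or 1 (3x3)")
  nt <- n_frames(series)
  fixed_center <- NULL
  if (fixed_location) {
    peak_frame <- which.max(vapply(seq_len(nt),
                                   function(i) max(get_frame(series, i)), 0))
    f <- get_frame(series, peak_frame)
    fixed_center <- arrayInd(which.max(f), dim(f))[1L, ]
  }
  vapply(seq_len(nt), function(i) {
    f <- get_frame(series, i)
    if (roi_half_width == 0L && !fixed_location) return(max(f))
    center <- fixed_center %||% arrayInd(which.max(f), dim(f))[1L, ]
    if (roi_half_width == 0L) f[matrix(center, 1L)] else
      roi_block_mean(f, center, roi_half_width)
  }, 0)
}

#' Curve comparison metrics: RMSE, maximum absolute difference, t-test p
#'
#' `rmse = sqrt(mean((truth - test)^2))`, `max_abs_diff = max|truth - test|`,
#' and the two-sided p-value of a pooled-variance two-sample t-test between
#' the two curves (treating time points as independent samples, as is common
#' for such monitoring curves despite their autocorrelation). Identical
#' curves give p = 1 by convention (the t statistic is degenerate).
#'
#' @param truth,test numeric curves of equal length >= 2
#' @return list with `rmse`, `max_abs_diff`, `t_test_p`
#' @export
curve_metrics <- function(truth, test) {
  if (length(truth) != length(test)) stop("curves must have equal length")
  if (length(truth) < 2L) stop("curves must have length >= 2")
  d <- truth - test
  rmse <- sqrt(mean(d^2))
  max_abs <- max(abs(d))
  pooled_sd <- sqrt((stats::var(truth) + stats::var(test)) / 2)
  p <- if (pooled_sd == 0) {
    if (mean(truth) == mean(test)) 1 else 0
  } else {
    stats::t.test(truth, test, var.equal = TRUE)$p.value
  }
  list(rmse = rmse, max_abs_diff = max_abs, t_test_p = p)
}

#' Background precision and accuracy of a temperature series
#'
#' Precision: the mean over ROI voxels of each voxel's temporal standard
#' deviation. Accuracy: the mean over ROI voxels of each voxel's temporal
#' RMSE with respect to 0 degC. The ROI must exclude heated tissue.
#'
#' @param series [temperature_series()]
#' @param background_roi logical array on the series' spatial grid, nonempty
#' @param exclude_baseline drop frame 1 (identically zero by construction for
#'   reconstructed data) before computing the temporal statistics
#'   (default TRUE)
#' @return list with `precision_c` and `accuracy_c` (degC)
#' @export
background_precision_accuracy <- function(series, background_roi,
                                          exclude_baseline = TRUE) {
  if (!inherits(series, "temperature_series"))
    stop("series must be a temperature_series")
  background_roi <- as_spatial_array(background_roi)
  d <- dim(series$frames)
  nd <- length(d) - 1L
  if (!identical(dim(background_roi), d[seq_len(nd)]))
    stop("background_roi must match the spatial grid")
  if (sum(background_roi) == 0L) stop("background_roi is empty")
  nt <- d[nd + 1L]
  mat <- matrix(series$frames, nrow = prod(d[seq_len(nd)]), ncol = nt)
  mat <- mat[as.logical(background_roi), , drop = FALSE]
  if (exclude_baseline && nt > 1L) mat <- mat[, -1L, drop = FALSE]
  if (ncol(mat) < 2L) stop("need at least two frames for temporal statistics")
  sds <- apply(mat, 1L, stats::sd)
  rmses <- sqrt(rowMeans(mat^2))
  list(precision_c = mean(sds), accuracy_c = mean(rmses))
}
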