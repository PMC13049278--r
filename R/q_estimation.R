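# Green's-function estimation of SAR and the deposited-power map Q from an
# observed early-heating temperature map, followed by the denoise / scale /
# crop refinement applied before the map is used in the forward model.

#' Deposited power density map
#'
#' Volumetric laser power deposition Q (W/m^3), referenced to the calibration
#' power at which it was derived. Values are identically zero outside
#' `crop_roi` once a crop has been applied.
#'
#' @param values numeric array (W/m^3)
#' @param spacing_mm voxel spacing per axis (mm)
#' @param crop_roi optional list with integer vectors `lo` and `hi` (voxel
#'   index box, inclusive) outside which values are zero
#' @param provenance named list (calibration power, input time, scale factor)
#' @return object of class `qmap`
#' @export
qmap <- function(values, spacing_mm, crop_roi = NULL, provenance = list()) {
  values <- as_spatial_array(values)
  if (any(!is.finite(values))) stop("Q values must be finite")
  nd <- length(dim(values))
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, nd)
  if (length(spacing_mm) != nd) stop("spacing_mm must match dimensionality")
  if (any(spacing_mm <= 0)) stop("all spacings must be positive")
  if (!is.null(crop_roi)) {
    if (length(crop_roi$lo) != nd || length(crop_roi$hi) != nd)
      stop("crop_roi must have lo/hi per axis")
    if (any(crop_roi$lo < 1L) || any(crop_roi$hi > dim(values)) ||
        any(crop_roi$lo > crop_roi$hi))
      stop("crop_roi must lie inside the grid")
  }
  structure(list(values = values, spacing_mm = as.numeric(spacing_mm),
                 crop_roi = crop_roi, provenance = provenance),
            class = "qmap")
}

#' @export
print.qmap <- function(x, ...) {
  cat(sprintf("Q map: %s voxels, max %.4g W/m^3%s\n",
              paste(dim(x$values), collapse = "x"), max(x$values),
              if (is.null(x$crop_roi)) "" else ", cropped"))
  invisible(x)
}

#' Estimate SAR from an early-heating temperature map
#'
#' Green's-function deconvolution of the bioheat equation: heating for a time
#' `t_in` from a spatially uniform baseline leaves the signature
#' `dT_hat = (SAR rho / (rho c)) * (1 - E)/a` per Fourier mode, with
#' `a = 4 pi^2 kappa |k|^2 + w/rho` and `E = exp(-a t_in)`. Inverting,
#'
#'   `SAR = c * IFFT[ dT_hat * a / (1 - exp(-a t_in)) ]`
#'
#' which for zero perfusion is the classical form
#' `4 pi^2 kappa c IFFT[dT_hat |k|^2 / (1 - exp(-4 pi^2 kappa t |k|^2))]`.
#' The singular DC ratio is replaced by its analytic limit `1/t_in`, so a
#' uniform temperature offset maps to `c * mean(dT) / t_in`.
#'
#' @param delta_t temperature change at the input time (degC), array
#' @param t_in_s elapsed heating time (s), > 0
#' @param props [tissue_properties()]
#' @param spacing_mm voxel spacing (mm)
#' @return SAR field (W/kg), numeric array
#' @export
estimate_sar <- function(delta_t, t_in_s, props, spacing_mm) {
  check_scalar(t_in_s, "t_in_s", positive = TRUE)
  delta_t <- as_spatial_array(delta_t)
  if (any(!is.finite(delta_t))) stop("temperature field must be finite")
  kg <- build_k_grid(dim(delta_t), spacing_mm)
  a <- 4 * pi^2 * thermal_diffusivity(props) * kg^2 + perfusion_rate(props)
  if (max(a) * t_in_s > 700)
    warning("kappa * t_in so large that the highest-|k| kernel has fully decayed; estimate is ill-conditioned")
  denom <- -expm1(-a * t_in_s)
  ratio <- ifelse(a * t_in_s < 1e-12, 1 / t_in_s, a / denom)
  sar <- ifftn(stats::fft(delta_t) * ratio) * props$specific_heat_j_kg_c
  resid <- max(abs(Im(sar))) / max(abs(sar), .Machine$double.eps)
  if (resid > 1e-6)
    warning(sprintf("imaginary residue %.2g above 1e-6 of magnitude", resid))
  array(Re(sar), dim = dim(delta_t))
}

#' Convert SAR (W/kg) to deposited power density Q (W/m^3)
#'
#' `Q = SAR * rho` voxel-wise.
#'
#' @param sar SAR field (W/kg)
#' @param props [tissue_properties()] (supplies the density), or a positive
#'   scalar density in kg/m^3
#' @param spacing_mm voxel spacing (mm)
#' @param provenance optional provenance list stored on the map
#' @return a [qmap()]
#' @export
sar_to_q <- function(sar, props, spacing_mm, provenance = list()) {
  rho <- if (inherits(props, "tissue_properties")) props$density_kg_m3 else props
  check_scalar(rho, "density", positive = TRUE)
  qmap(as_spatial_array(sar) * rho, spacing_mm, provenance = provenance)
}

#' Box median filter with reflected edges
#'
#' Plain `size^d` running median over a 2D or 3D array, edges handled by
#' reflection. Vectorized (single sort over all neighborhoods).
#'
#' @param x numeric 2D or 3D array
#' @param size odd box width per axis (default 3)
#' @return filtered array, same dimensions
#' @export
median_filter_box <- function(x, size = 3L) {
  x <- as_spatial_array(x)
  if (size %% 2L != 1L || size < 1L) stop("size must be odd and >= 1")
  if (size == 1L) return(x)
  dims <- dim(x)
  nd <- length(dims)
  if (nd > 3L) stop("only 2D and 3D arrays are supported")
  h <- (size - 1L) %/% 2L
  # reflect-pad each axis by h
  pad_idx <- lapply(dims, function(n) {
    c(rev(seq_len(min(h, n))), seq_len(n), n + 1L - rev(seq_len(min(h, n))))
  })
  xp <- do.call(`[`, c(list(x), pad_idx, list(drop = FALSE)))
  offsets <- as.matrix(expand.grid(rep(list(0:(size - 1L)), nd)))
  n <- prod(dims)
  m <- matrix(0, nrow = n, ncol = nrow(offsets))
  for (j in seq_len(nrow(offsets))) {
    idx <- lapply(seq_len(nd), function(ax) offsets[j, ax] + seq_len(dims[ax]))
    m[, j] <- as.numeric(do.call(`[`, c(list(xp), idx, list(drop = FALSE))))
  }
  k <- ncol(m)
  sorted <- matrix(m[order(row(m), m)], nrow = n, byrow = TRUE)
  mid <- (k + 1L) %/% 2L
  med <- if (k %% 2L == 1L) sorted[, mid] else (sorted[, mid] + sorted[, mid + 1L]) / 2
  array(med, dim = dims)
}

#' Default crop box around the heat source
#'
#' A box grown outward from the hottest Q voxel: each face advances while the
#' adjacent slab still contains a voxel above `threshold_frac * max(Q)`, then
#' the box is dilated by a margin and clamped to the grid. Growing from the
#' peak (rather than taking the global bounding box of supra-threshold voxels)
#' keeps the box tight around the main deposition lobe even when isolated
#' deconvolution-noise voxels elsewhere exceed the threshold — the automated
#' analog of drawing the region of interest around the applicator by hand.
#'
#' @param values Q array with a positive maximum
#' @param threshold_frac fraction of max defining the support (default 0.05)
#' @param dilate_voxels margin in voxels (default 3)
#' @return list(lo, hi) integer vectors
#' @export
default_crop_roi <- function(values, threshold_frac = 0.05, dilate_voxels = 3L) {
  values <- as_spatial_array(values)
  dims <- dim(values)
  mx <- max(values)
  if (mx <= 0) stop("Q has no positive values; cannot derive crop ROI")
  above <- values > threshold_frac * mx
  peak <- arrayInd(which.max(values), dims)[1L, ]
  lo <- hi <- as.integer(peak)
  slab_any <- function(ax, at) {
    idx <- lapply(seq_along(dims), function(a2)
      if (a2 == ax) at else lo[a2]:hi[a2])
    any(do.call(`[`, c(list(above), idx, list(drop = FALSE))))
  }
  repeat {
    grew <- FALSE
    for (ax in seq_along(dims)) {
      if (lo[ax] > 1L && slab_any(ax, lo[ax] - 1L)) {
        lo[ax] <- lo[ax] - 1L; grew <- TRUE
      }
      if (hi[ax] < dims[ax] && slab_any(ax, hi[ax] + 1L)) {
        hi[ax] <- hi[ax] + 1L; grew <- TRUE
      }
    }
    if (!grew) break
  }
  list(lo = as.integer(pmax(lo - dilate_voxels, 1L)),
       hi = as.integer(pmin(hi + dilate_voxels, dims)))
}

# Zero an array outside an roi box.
apply_crop <- function(values, roi) {
  dims <- dim(values)
  keep <- array(FALSE, dim = dims)
  idx <- lapply(seq_along(dims), function(ax) roi$lo[ax]:roi$hi[ax])
  keep <- do.call(`[<-`, c(list(keep), idx, list(TRUE)))
  values * keep
}

#' Refine a raw Q estimate: median filter, hottest-voxel scaling, crop
#'
#' Applies, in order: (1) a box median filter (3 voxels per axis) to suppress
#' deconvolution noise; (2) a forward simulation of the calibration heating
#' with the filtered map; (3) a global rescaling by
#' `max(observed dT) / max(simulated dT)` so the simulated maximum equals the
#' observed maximum of the calibration heating; (4) zeroing outside a crop box
#' around the source. The scale factor is recorded in the map's provenance.
#' The output is invariant to pre-scaling of `q_raw` by any positive constant
#' (the hottest-voxel scaling cancels it).
#'
#' @param q_raw uncropped [qmap()] from [sar_to_q()]
#' @param calibration_series [temperature_series()] of the calibration heating
#'   the map was derived from
#' @param props [tissue_properties()]
#' @param schedule [power_schedule()] of the calibration heating
#' @param crop_roi optional list(lo, hi); default from [default_crop_roi()]
#' @param median_filter apply the median filter step (default TRUE)
#' @return refined [qmap()]
#' @export
refine_q <- function(q_raw, calibration_series, props, schedule,
                     crop_roi = NULL, median_filter = TRUE) {
  if (!inherits(q_raw, "qmap")) stop("q_raw must be a qmap")
  if (!inherits(calibration_series, "temperature_series"))
    stop("calibration_series must be a temperature_series")
  v <- q_raw$values
  if (median_filter) v <- median_filter_box(v, 3L)
  sim <- simulate_heating(0, v, props, schedule,
                          calibration_series$frame_interval_s,
                          n_frames(calibration_series),
                          spacing_mm = q_raw$spacing_mm)
  max_sim <- max(sim$frames)
  if (max_sim <= 0) stop("simulated calibration heating has no positive temperature; cannot scale")
  s <- max(calibration_series$frames) / max_sim
  v <- v * s
  roi <- crop_roi %||% default_crop_roi(v)
  v <- apply_crop(v, roi)
  prov <- q_raw$provenance
  prov$scale_factor <- s
  qmap(v, q_raw$spacing_mm, crop_roi = roi, provenance = prov)
}

#' One-call Q estimation from a calibration heating series
#'
#' Convenience wrapper: picks the calibration dynamic (default the first
#' heating frame, which gives the lowest-error Green's-function estimate),
#' deconvolves SAR, converts to Q, and refines (filter, scale, crop).
#'
#' @param calibration_series [temperature_series()] of the calibration run
#'   (frame 1 = pre-heating baseline)
#' @param props [tissue_properties()]
#' @param schedule calibration [power_schedule()]
#' @param dynamic_index which heating dynamic to use (1 = first frame after
#'   baseline); the input time is `dynamic_index * frame_interval`
#' @param ... passed to [refine_q()]
#' @return refined [qmap()] with provenance
#' @export
estimate_q <- function(calibration_series, props, schedule,
                       dynamic_index = 1L, ...) {
  if (dynamic_index < 1L || dynamic_index >= n_frames(calibration_series))
    stop("dynamic_index out of range")
  t_in <- dynamic_index * calibration_series$frame_interval_s
  dT <- get_frame(calibration_series, dynamic_index + 1L)
  sar <- estimate_sar(dT, t_in, props, calibration_series$spacing_mm)
  q_raw <- sar_to_q(sar, props, calibration_series$spacing_mm,
                    provenance = list(
                      calibration_power_w = schedule$calibration_power_w,
                      t_in_s = t_in, dynamic_index = dynamic_index))
  refine_q(q_raw, calibration_series, props, schedule, ...)
}
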