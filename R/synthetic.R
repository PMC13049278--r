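# Digital phantom generator: laser-like deposited-power fields, truth heatings
# via the forward model, complex image series with calibrated Gaussian noise,
# and full Cartesian k-space — so every pipeline stage runs without scanner
# data.

#' Digital phantom specification
#'
#' An ellipsoidal object (gellan-gum-like or head-like) centered in the grid,
#' with uniform baseline signal magnitude inside and zero outside.
#'
#' @param dims voxel counts per axis (2 or 3 axes)
#' @param spacing_mm voxel spacing per axis (mm)
#' @param baseline_magnitude signal magnitude inside the object (arbitrary
#'   units, default 100)
#' @param props [tissue_properties()] of the object material
#' @param object_semiaxes_frac ellipsoid semi-axes as a fraction of each
#'   half-extent (default 1: the inscribed ellipsoid, which occupies ~52% of
#'   the grid in 3D)
#' @return object of class `phantom_spec` with the analytic geometry and the
#'   voxelized `object_mask`
#' @export
phantom_spec <- function(dims, spacing_mm, baseline_magnitude = 100,
                         props = gellan_gum_properties(),
                         object_semiaxes_frac = 1) {
  nd <- length(dims)
  if (!nd %in% c(2L, 3L)) stop("dims must have 2 or 3 axes")
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, nd)
  if (any(spacing_mm <= 0)) stop("all spacings must be positive")
  check_scalar(baseline_magnitude, "baseline_magnitude", positive = TRUE)
  semi_mm <- object_semiaxes_frac * dims * spacing_mm / 2
  # voxel-center coordinates, grid center at 0 mm
  coords <- lapply(seq_len(nd), function(ax)
    (seq_len(dims[ax]) - 1 - (dims[ax] - 1) / 2) * spacing_mm[ax])
  r2 <- array(0, dim = dims)
  for (ax in seq_len(nd)) {
    f <- (coords[[ax]] / semi_mm[ax])^2
    r2 <- r2 + f[slice.index(r2, ax)]
  }
  mask <- r2 <= 1
  if (mean(mask) < 0.5)
    stop("object must occupy at least 50% of the grid; enlarge object_semiaxes_frac")
  structure(list(dims = as.integer(dims), spacing_mm = as.numeric(spacing_mm),
                 baseline_magnitude = baseline_magnitude, props = props,
                 semiaxes_mm = semi_mm, object_mask = mask, coords_mm = coords),
            class = "phantom_spec")
}

#' Laser applicator specification
#'
#' A diffusing-tip surrogate: power is deposited with exponential radial decay
#' around a line segment of the given emitting length, centered on
#' `tip_position_mm` and oriented along `orientation`.
#'
#' @param peak_power_density_w_m3 deposited power density on the segment at
#'   calibration power (W/m^3)
#' @param tip_position_mm segment midpoint in mm (grid center at 0); default
#'   the grid center
#' @param orientation direction vector (normalized internally); default along
#'   the last grid axis
#' @param emitting_length_mm length of the emitting segment (mm, default 10,
#'   a common diffusing-tip length)
#' @param radial_decay_length_mm e-folding length of the radial decay (mm)
#' @return object of class `laser_spec`
#' @export
laser_spec <- function(peak_power_density_w_m3, tip_position_mm = NULL,
                       orientation = NULL, emitting_length_mm = 10,
                       radial_decay_length_mm = 3) {
  check_scalar(peak_power_density_w_m3, "peak_power_density_w_m3", positive = TRUE)
  check_scalar(emitting_length_mm, "emitting_length_mm", positive = TRUE)
  check_scalar(radial_decay_length_mm, "radial_decay_length_mm", positive = TRUE)
  structure(list(peak_power_density_w_m3 = peak_power_density_w_m3,
                 tip_position_mm = tip_position_mm,
                 orientation = orientation,
                 emitting_length_mm = emitting_length_mm,
                 radial_decay_length_mm = radial_decay_length_mm),
            class = "laser_spec")
}

#' Build a deposited-power map from a laser specification
#'
#' `Q = peak * exp(-d / decay_length)` with `d` the distance from each voxel
#' center to the emitting segment; zero outside the phantom object.
#'
#' @param laser [laser_spec()]
#' @param phantom [phantom_spec()]
#' @return a [qmap()]
#' @export
make_laser_q <- function(laser, phantom) {
  nd <- length(phantom$dims)
  tip <- laser$tip_position_mm %||% rep(0, nd)
  orient <- laser$orientation %||% c(rep(0, nd - 1L), 1)
  if (length(tip) != nd || length(orient) != nd)
    stop("laser geometry must match the phantom dimensionality")
  u <- orient / sqrt(sum(orient^2))
  L <- laser$emitting_length_mm
  a_end <- tip - u * L / 2
  b_end <- tip + u * L / 2
  inside <- function(p) sum((p / phantom$semiaxes_mm)^2) <= 1
  if (!inside(a_end) || !inside(b_end))
    stop("emitting segment must lie entirely inside the phantom object")

  dims <- phantom$dims
  coords <- phantom$coords_mm
  # distance from every voxel center to the segment [a_end, b_end]
  vproj <- array(0, dim = dims)   # (p - a) . u
  d2 <- array(0, dim = dims)      # |p - a|^2
  for (ax in seq_len(nd)) {
    ca <- coords[[ax]] - a_end[ax]
    vproj <- vproj + (ca * u[ax])[slice.index(vproj, ax)]
    d2 <- d2 + (ca^2)[slice.index(d2, ax)]
  }
  s <- pmin(pmax(vproj, 0), L)
  dist <- sqrt(pmax(d2 - 2 * s * vproj + s^2, 0))
  q <- laser$peak_power_density_w_m3 * exp(-dist / laser$radial_decay_length_mm)
  q[!phantom$object_mask] <- 0
  qmap(q, phantom$spacing_mm,
       provenance = list(source = "synthetic laser capsule"))
}

#' Complex noise level for a target temperature precision
#'
#' At high SNR the phase noise of a complex voxel is `sd_complex / magnitude`
#' (per real/imaginary component), so the single-frame temperature noise is
#' `sd_complex / (magnitude * |prf coefficient|)`. The temporal standard
#' deviation of a reconstructed temperature series equals this single-frame
#' value (the baseline frame's phase noise is a constant offset across the
#' series and drops out of the temporal SD), so the component noise that
#' yields a measured precision of `target` is
#' `sd = magnitude * |coef| * target`. Validated by Monte-Carlo closure in
#' the test suite.
#'
#' @param target_temp_precision_c desired background precision (degC), >= 0
#' @param baseline_magnitude object signal magnitude
#' @param acq [acquisition_params()]
#' @return per-component complex Gaussian noise SD (signal units)
#' @export
noise_sd_for_precision <- function(target_temp_precision_c, baseline_magnitude,
                                   acq) {
  check_scalar(target_temp_precision_c, "target_temp_precision_c", nonneg = TRUE)
  check_scalar(baseline_magnitude, "baseline_magnitude", positive = TRUE)
  baseline_magnitude * abs(prf_coefficient(acq)) * target_temp_precision_c
}

#' Simulate a complete heating experiment
#'
#' Generates the truth temperature series with the forward bioheat model, the
#' complex image dynamics (baseline magnitude, PRF phase from the truth, plus
#' i.i.d. circular complex Gaussian noise), and the fully sampled k-space of
#' every dynamic. Deterministic given the seed.
#'
#' @param phantom [phantom_spec()]
#' @param laser [laser_spec()]
#' @param schedule [power_schedule()] (treatment powers; the source is the
#'   laser Q scaled by `P(t)/calibration_power`)
#' @param acq [acquisition_params()]
#' @param noise list with `seed` and either `target_temp_precision_c` (the
#'   component SD is derived via [noise_sd_for_precision()]) or
#'   `complex_noise_sd`
#' @param n_frames number of dynamics including the pre-heating baseline
#' @return list with `truth` ([temperature_series()]), `frames` (list of
#'   [complex_image_frame()]), `kspace` (list of fully sampled
#'   [kspace_frame()]), `q` (the generating [qmap()]), and `noise_sd`
#' @export
simulate_experiment <- function(phantom, laser, schedule, acq, noise,
                                n_frames) {
  if (!is.list(noise) || is.null(noise$seed))
    stop("noise must be a list with a 'seed'")
  has_target <- !is.null(noise$target_temp_precision_c)
  has_sd <- !is.null(noise$complex_noise_sd)
  if (has_target == has_sd)
    stop("exactly one of target_temp_precision_c / complex_noise_sd must be given")
  sd <- if (has_sd) noise$complex_noise_sd else
    noise_sd_for_precision(noise$target_temp_precision_c,
                           phantom$baseline_magnitude, acq)
  q <- make_laser_q(laser, phantom)
  truth <- simulate_heating(0, q, phantom$props, schedule,
                            acq$frame_interval_s, n_frames)
  mag <- phantom$baseline_magnitude * phantom$object_mask
  coef <- prf_coefficient(acq)
  dims <- phantom$dims
  nvox <- prod(dims)
  frames <- vector("list", n_frames)
  kspace <- vector("list", n_frames)
  with_local_seed(noise$seed, {
    for (n in seq_len(n_frames)) {
      clean <- mag * exp(1i * coef * get_frame(truth, n))
      eps <- if (sd > 0)
        complex(real = stats::rnorm(nvox, 0, sd),
                imaginary = stats::rnorm(nvox, 0, sd)) else 0i
      frames[[n]] <- complex_image_frame(array(clean + eps, dim = dims),
                                         frame_index = n - 1L)
      kspace[[n]] <- image_to_kspace(frames[[n]])
    }
  })
  list(truth = truth, frames = frames, kspace = kspace, q = q, noise_sd = sd)
}

#' Perturb the thermal model for robustness studies
#'
#' Returns scaled copies of the deposited-power map and tissue properties
#' (fractional errors in Q and in the thermal conductivity, hence
#' diffusivity); the originals are untouched.
#'
#' @param q [qmap()]
#' @param kappa_error fractional conductivity error (> -1); 0.5 means +50%
#' @param q_error fractional Q error (> -1)
#' @param props [tissue_properties()]
#' @return list with perturbed `q` and `props`
#' @export
perturb_model <- function(q, kappa_error, q_error, props) {
  check_scalar(kappa_error, "kappa_error")
  check_scalar(q_error, "q_error")
  if (kappa_error <= -1 || q_error <= -1) stop("errors must be > -1")
  q2 <- qmap(q$values * (1 + q_error), q$spacing_mm, crop_roi = q$crop_roi,
             provenance = c(q$provenance, list(q_error = q_error)))
  props2 <- tissue_properties(props$density_kg_m3, props$specific_heat_j_kg_c,
                              props$conductivity_w_m_c * (1 + kappa_error),
                              props$perfusion_kg_m3_s, props$arterial_temp_c)
  list(q = q2, props = props2)
}
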