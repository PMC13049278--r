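# Forward solution of the Pennes bioheat equation (PBHE) on a regular grid.
#
# The model is solved for the temperature *change* dT relative to a constant
# baseline, so the perfusion term -w c (T - Tar) acts on dT with the arterial
# temperature folded into the baseline:
#
#   rho c d(dT)/dt = lambda Laplacian(dT) - w c dT + P(t)/P_cal * Q
#
# On a periodic grid this is diagonal in the Fourier domain, which permits an
# exact exponential-integrator update per time step for piecewise-constant
# laser power. An explicit finite-difference stepper is provided as an
# independent cross-check.

#' Tissue thermal properties
#'
#' Container for the homogeneous tissue parameters of the bioheat model.
#' The thermal diffusivity is always derived as `conductivity / (density *
#' specific_heat)` and never stored independently.
#'
#' @param density_kg_m3 tissue density rho (kg/m^3)
#' @param specific_heat_j_kg_c specific heat c (J/(kg.degC))
#' @param conductivity_w_m_c thermal conductivity lambda (W/(m.degC))
#' @param perfusion_kg_m3_s Pennes perfusion constant w (kg/(m^3.s)); default 0
#' @param arterial_temp_c arterial blood temperature (degC); only meaningful
#'   relative to the (arbitrary) baseline and unused when `perfusion` is 0
#' @return object of class `tissue_properties`
#' @seealso [gellan_gum_properties()], [brain_properties()],
#'   [thermal_diffusivity()]
#' @export
tissue_properties <- function(density_kg_m3, specific_heat_j_kg_c,
                              conductivity_w_m_c, perfusion_kg_m3_s = 0,
                              arterial_temp_c = 37) {
  check_scalar(density_kg_m3, "density_kg_m3", positive = TRUE)
  check_scalar(specific_heat_j_kg_c, "specific_heat_j_kg_c", positive = TRUE)
  check_scalar(conductivity_w_m_c, "conductivity_w_m_c", positive = TRUE)
  check_scalar(perfusion_kg_m3_s, "perfusion_kg_m3_s", nonneg = TRUE)
  check_scalar(arterial_temp_c, "arterial_temp_c")
  structure(list(density_kg_m3 = density_kg_m3,
                 specific_heat_j_kg_c = specific_heat_j_kg_c,
                 conductivity_w_m_c = conductivity_w_m_c,
                 perfusion_kg_m3_s = perfusion_kg_m3_s,
                 arterial_temp_c = arterial_temp_c),
            class = "tissue_properties")
}

#' Thermal diffusivity kappa = lambda / (rho c), in m^2/s
#' @param props a [tissue_properties()] object
#' @export
thermal_diffusivity <- function(props) {
  props$conductivity_w_m_c /
    (props$density_kg_m3 * props$specific_heat_j_kg_c)
}

# Perfusion decay constant w/rho (1/s)
perfusion_rate <- function(props) {
  props$perfusion_kg_m3_s / props$density_kg_m3
}

#' Literature thermal properties for gellan gum brain phantom material
#' (rho 1030 kg/m^3, c 4186 J/(kg.degC), lambda 0.56 W/(m.degC), no perfusion)
#' @export
gellan_gum_properties <- function() {
  tissue_properties(1030, 4186, 0.56, perfusion_kg_m3_s = 0)
}

#' Literature thermal properties for brain tissue
#' (rho 1046 kg/m^3, c 3630 J/(kg.degC), lambda 0.51 W/(m.degC), no perfusion)
#' @export
brain_properties <- function() {
  tissue_properties(1046, 3630, 0.51, perfusion_kg_m3_s = 0)
}

#' @export
print.tissue_properties <- function(x, ...) {
  cat(sprintf(paste0("Tissue properties: rho %.0f kg/m^3, c %.0f J/(kg.C), ",
                     "lambda %.3g W/(m.C), w %.3g kg/(m^3.s)\n",
                     "  diffusivity kappa = %.4g m^2/s\n"),
              x$density_kg_m3, x$specific_heat_j_kg_c, x$conductivity_w_m_c,
              x$perfusion_kg_m3_s, thermal_diffusivity(x)))
  invisible(x)
}

#' Laser power schedule
#'
#' Ordered piecewise-constant laser power segments, plus the calibration power
#' at which the deposited-power map Q was (or will be) derived. During forward
#' simulation the source term is `Q * P(t) / calibration_power` (deposition
#' scales linearly with applied power). Power is zero after the last segment
#' (laser off).
#'
#' @param durations_s segment durations (s), all > 0
#' @param powers_w segment powers (W), all >= 0
#' @param calibration_power_w power (W) at which Q is referenced; > 0
#' @return object of class `power_schedule`
#' @export
power_schedule <- function(durations_s, powers_w, calibration_power_w) {
  if (length(durations_s) == 0L) stop("schedule must have at least one segment")
  if (length(durations_s) != length(powers_w))
    stop("durations_s and powers_w must have the same length")
  if (any(!is.finite(durations_s)) || any(durations_s <= 0))
    stop("all segment durations must be positive")
  if (any(!is.finite(powers_w)) || any(powers_w < 0))
    stop("all segment powers must be >= 0")
  check_scalar(calibration_power_w, "calibration_power_w", positive = TRUE)
  structure(list(durations_s = as.numeric(durations_s),
                 powers_w = as.numeric(powers_w),
                 calibration_power_w = calibration_power_w),
            class = "power_schedule")
}

#' Constant-power schedule helper
#' @param power_w applied power (W)
#' @param duration_s heating duration (s)
#' @param calibration_power_w reference power for Q (default: `power_w`)
#' @export
constant_schedule <- function(power_w, duration_s,
                              calibration_power_w = power_w) {
  power_schedule(duration_s, power_w, calibration_power_w)
}

# End times of each segment.
schedule_breaks <- function(schedule) cumsum(schedule$durations_s)

#' Laser power at time t (0 after the last segment)
#' @param schedule a [power_schedule()]
#' @param t_s time(s) in seconds, measured from schedule start
#' @return power in W, vectorized over `t_s`
#' @export
power_at <- function(schedule, t_s) {
  breaks <- c(0, schedule_breaks(schedule))
  idx <- findInterval(t_s, breaks, left.open = TRUE, rightmost.closed = FALSE)
  p <- c(schedule$powers_w, 0)
  idx[idx == 0L] <- 1L                      # t = 0 belongs to the first segment
  idx[idx > length(schedule$powers_w)] <- length(p)
  p[idx]
}

#' Temperature-change time series
#'
#' Per-voxel temperature change (degC, relative to the pre-heating baseline)
#' over time. Frames are stored in one array whose last dimension is time;
#' frame 1 is the baseline (all zeros for simulated data).
#'
#' @param frames numeric array with time as the last dimension (2D data:
#'   `nx x ny x nt`; 3D data: `nx x ny x nz x nt`)
#' @param spacing_mm voxel spacing per spatial axis (mm)
#' @param frame_interval_s time between frames (s)
#' @return object of class `temperature_series`
#' @export
temperature_series <- function(frames, spacing_mm, frame_interval_s) {
  frames <- as_spatial_array(frames)
  nd <- length(dim(frames)) - 1L
  if (nd < 1L) stop("frames must have a time dimension")
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, nd)
  if (length(spacing_mm) != nd)
    stop("spacing_mm must have one entry per spatial axis")
  if (any(spacing_mm <= 0)) stop("all spacings must be positive")
  check_scalar(frame_interval_s, "frame_interval_s", positive = TRUE)
  if (any(!is.finite(frames))) stop("all temperature values must be finite")
  structure(list(frames = frames,
                 spacing_mm = as.numeric(spacing_mm),
                 frame_interval_s = frame_interval_s),
            class = "temperature_series")
}

#' @export
print.temperature_series <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("Temperature series: %s voxels, %d frames @ %.3g s, max dT %.2f C\n",
              paste(d[-length(d)], collapse = "x"), d[length(d)],
              x$frame_interval_s, max(x$frames)))
  invisible(x)
}

#' Number of frames in a temperature series
#' @param series a [temperature_series()]
#' @export
n_frames <- function(series) {
  d <- dim(series$frames)
  d[length(d)]
}

#' Extract one spatial frame from a temperature series
#' @param series a [temperature_series()]
#' @param i frame index (1 = baseline)
#' @return numeric array with the series' spatial dimensions
#' @export
get_frame <- function(series, i) {
  d <- dim(series$frames)
  nd <- length(d) - 1L
  if (i < 1L || i > d[nd + 1L]) stop("frame index out of range")
  args <- c(rep(list(quote(expr = )), nd), list(i))
  out <- do.call(`[`, c(list(series$frames), args, list(drop = FALSE)))
  array(out, dim = d[seq_len(nd)])
}

#' Spatial-frequency magnitude grid
#'
#' Builds the field |k| (cycles/m) on the discrete Fourier grid of an image
#' with the given voxel counts and spacings, in standard DFT order (value 0
#' exactly at the DC index, symmetric under frequency negation).
#'
#' @param dims voxel counts per axis
#' @param spacing_mm voxel spacing per axis in mm (scalar recycled)
#' @return numeric array of dimension `dims` with |k| in cycles/m
#' @export
build_k_grid <- function(dims, spacing_mm) {
  if (any(dims < 1L)) stop("dims must be >= 1 per axis")
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, length(dims))
  if (length(spacing_mm) != length(dims))
    stop("spacing_mm must match dims")
  if (any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("all spacings must be positive")
  spacing_m <- spacing_mm / 1000
  k2 <- array(0, dim = dims)
  for (ax in seq_along(dims)) {
    f2 <- fft_freq(dims[ax], spacing_m[ax])^2
    k2 <- k2 + f2[slice.index(k2, ax)]
  }
  sqrt(k2)
}

#' Spectral heat propagator
#'
#' Per-mode decay factor of the Green's function of the bioheat equation over
#' an interval `t`: `exp(-4 pi^2 kappa t |k|^2) * exp(-(w/rho) t)`. This is
#' the Fourier transform of the (perfusion-damped) Gaussian heat kernel.
#'
#' @param k_grid |k| field from [build_k_grid()] (cycles/m)
#' @param kappa_m2_s thermal diffusivity (m^2/s), >= 0
#' @param t_s elapsed time (s), >= 0
#' @param w_over_rho_per_s perfusion decay constant w/rho (1/s), >= 0
#' @return object of class `heat_propagator` with fields `decay` (array in
#'   (0, 1]) and the generating parameters
#' @export
heat_propagator <- function(k_grid, kappa_m2_s, t_s, w_over_rho_per_s = 0) {
  check_scalar(kappa_m2_s, "kappa_m2_s", nonneg = TRUE)
  check_scalar(t_s, "t_s", nonneg = TRUE)
  check_scalar(w_over_rho_per_s, "w_over_rho_per_s", nonneg = TRUE)
  decay <- exp(-(4 * pi^2 * kappa_m2_s * k_grid^2 + w_over_rho_per_s) * t_s)
  structure(list(decay = decay, kappa_m2_s = kappa_m2_s, t_s = t_s,
                 w_over_rho_per_s = w_over_rho_per_s),
            class = "heat_propagator")
}

# Core spectral update, frequency domain in, frequency domain out.
# dT_hat_{n+1} = dT_hat * E + power_scale * q_hat/(rho c) * (1 - E)/a,
# with a = 4 pi^2 kappa |k|^2 + w/rho and the DC limit (1-E)/a -> dt.
spectral_step_hat <- function(dT_hat, q_hat, a, dt, rho_c, power_scale) {
  E <- exp(-a * dt)
  ratio <- ifelse(a * dt < 1e-12, dt, -expm1(-a * dt) / a)
  dT_hat * E + (power_scale / rho_c) * q_hat * ratio
}

#' Advance the temperature field by one time step (spectral, exact)
#'
#' Exact exponential-integrator update of the bioheat equation on a periodic
#' grid with the source held constant over the step. Temperature is relative
#' to the baseline, so arterial-temperature terms vanish.
#'
#' @param delta_t temperature-change field (degC), array
#' @param q deposited power density Q (W/m^3), array or [qmap()], same grid
#' @param props [tissue_properties()]
#' @param power_scale dimensionless source multiplier `P(t)/P_cal`, >= 0
#' @param dt_s step duration (s), > 0
#' @param spacing_mm voxel spacing (mm); required unless `q` is a [qmap()]
#' @return updated temperature-change array
#' @export
step_temperature <- function(delta_t, q, props, power_scale, dt_s,
                             spacing_mm = NULL) {
  q_values <- if (inherits(q, "qmap")) q$values else as_spatial_array(q)
  spacing_mm <- spacing_mm %||% (if (inherits(q, "qmap")) q$spacing_mm else NULL)
  if (is.null(spacing_mm)) stop("spacing_mm is required")
  delta_t <- as_spatial_array(delta_t)
  if (!same_dims(delta_t, q_values)) stop("Q grid must match temperature grid")
  check_scalar(dt_s, "dt_s", positive = TRUE)
  check_scalar(power_scale, "power_scale", nonneg = TRUE)
  kg <- build_k_grid(dim(delta_t), spacing_mm)
  a <- 4 * pi^2 * thermal_diffusivity(props) * kg^2 + perfusion_rate(props)
  rho_c <- props$density_kg_m3 * props$specific_heat_j_kg_c
  out <- ifftn(spectral_step_hat(stats::fft(delta_t), stats::fft(q_values),
                                 a, dt_s, rho_c, power_scale))
  array(Re(out), dim = dim(delta_t))
}

# Split the interval [t0, t1] at schedule segment boundaries; returns a
# data.frame of sub-steps with constant power.
substeps_for_interval <- function(schedule, t0, t1) {
  breaks <- schedule_breaks(schedule)
  cuts <- sort(unique(c(t0, breaks[breaks > t0 & breaks < t1], t1)))
  starts <- cuts[-length(cuts)]
  ends <- cuts[-1L]
  mid <- (starts + ends) / 2
  data.frame(dt = ends - starts, power_w = power_at(schedule, mid))
}

#' Simulate a full heating experiment
#'
#' Repeated spectral stepping with `power_scale = P(t)/calibration_power`,
#' sub-stepping at power-segment boundaries so every sub-step has constant
#' power. Frames are reported at multiples of `frame_interval_s`; frame 1 is
#' the initial condition at time 0.
#'
#' @param delta_t0 initial temperature-change field (degC); scalar 0 is
#'   expanded to the Q grid
#' @param q deposited power density at calibration power ([qmap()] or array)
#' @param props [tissue_properties()]
#' @param schedule [power_schedule()]
#' @param frame_interval_s time between reported frames (s)
#' @param n_frames number of frames including the baseline frame
#' @param spacing_mm voxel spacing (mm); taken from `q` if it is a [qmap()]
#' @return a [temperature_series()]
#' @export
simulate_heating <- function(delta_t0, q, props, schedule, frame_interval_s,
                             n_frames, spacing_mm = NULL) {
  if (!inherits(schedule, "power_schedule")) stop("schedule must be a power_schedule")
  q_values <- if (inherits(q, "qmap")) q$values else as_spatial_array(q)
  spacing_mm <- spacing_mm %||% (if (inherits(q, "qmap")) q$spacing_mm else NULL)
  if (is.null(spacing_mm)) stop("spacing_mm is required")
  check_scalar(frame_interval_s, "frame_interval_s", positive = TRUE)
  if (n_frames < 1L) stop("n_frames must be >= 1")
  dims <- dim(q_values)
  if (length(delta_t0) == 1L) delta_t0 <- array(delta_t0, dim = dims)
  delta_t0 <- as_spatial_array(delta_t0)
  if (!same_dims(delta_t0, q_values)) stop("initial field must match Q grid")

  kg <- build_k_grid(dims, spacing_mm)
  a <- 4 * pi^2 * thermal_diffusivity(props) * kg^2 + perfusion_rate(props)
  rho_c <- props$density_kg_m3 * props$specific_heat_j_kg_c
  q_hat <- stats::fft(q_values)
  p_cal <- schedule$calibration_power_w

  frames <- array(0, dim = c(dims, n_frames))
  nvox <- prod(dims)
  frames[seq_len(nvox)] <- delta_t0
  dT_hat <- stats::fft(delta_t0)
  for (n in seq_len(n_frames - 1L)) {
    ss <- substeps_for_interval(schedule, (n - 1) * frame_interval_s,
                                n * frame_interval_s)
    for (j in seq_len(nrow(ss))) {
      dT_hat <- spectral_step_hat(dT_hat, q_hat, a, ss$dt[j], rho_c,
                                  ss$power_w[j] / p_cal)
    }
    frames[n * nvox + seq_len(nvox)] <- Re(ifftn(dT_hat))
  }
  temperature_series(frames, spacing_mm, frame_interval_s)
}

#' Explicit finite-difference reference step (test oracle)
#'
#' Independent 7-point-stencil (3D; 5-point in 2D, 3-point in 1D) explicit
#' Euler discretization of the bioheat equation on a periodic grid. Used to
#' cross-check the spectral stepper; second-order in space, first-order in
#' time, subject to the usual explicit stability bound
#' `dt <= min(spacing)^2 / (2 D kappa)` with `D` the dimensionality.
#'
#' @inheritParams step_temperature
#' @export
fd_reference_step <- function(delta_t, q, props, power_scale, dt_s,
                              spacing_mm = NULL) {
  q_values <- if (inherits(q, "qmap")) q$values else as_spatial_array(q)
  spacing_mm <- spacing_mm %||% (if (inherits(q, "qmap")) q$spacing_mm else NULL)
  if (is.null(spacing_mm)) stop("spacing_mm is required")
  delta_t <- as_spatial_array(delta_t)
  if (!same_dims(delta_t, q_values)) stop("Q grid must match temperature grid")
  check_scalar(dt_s, "dt_s", positive = TRUE)
  dims <- dim(delta_t)
  nd <- length(dims)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, nd)
  spacing_m <- spacing_mm / 1000
  kappa <- thermal_diffusivity(props)
  if (kappa > 0) {
    dt_max <- min(spacing_m)^2 / (2 * nd * kappa)
    if (dt_s > dt_max)
      stop(sprintf("dt %.3g s violates the explicit stability bound %.3g s",
                   dt_s, dt_max))
  }
  lap <- array(0, dim = dims)
  for (ax in seq_len(nd)) {
    lap <- lap + (axshift(delta_t, ax, 1L) + axshift(delta_t, ax, -1L) -
                    2 * delta_t) / spacing_m[ax]^2
  }
  rho_c <- props$density_kg_m3 * props$specific_heat_j_kg_c
  delta_t + dt_s * (kappa * lap - perfusion_rate(props) * delta_t +
                      power_scale * q_values / rho_c)
}
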