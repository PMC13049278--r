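# Proton-resonance-frequency (PRF) shift thermometry: conversions between
# temperature change and image phase, and construction of the model-predicted
# complex frame used to synthesize k-space.

#' MR acquisition parameters for PRF thermometry
#'
#' @param b0_t main field strength B0 (T)
#' @param te_s echo time TE (s)
#' @param frame_interval_s time between dynamics (s)
#' @param gamma_hz_per_t gyromagnetic ratio (Hz/T); default 42.577e6
#' @param alpha_ppm_per_c PRF coefficient (ppm/degC); default -0.01 (aqueous
#'   tissue: heating lowers the resonance frequency)
#' @return object of class `acquisition_params`
#' @export
acquisition_params <- function(b0_t, te_s, frame_interval_s,
                               gamma_hz_per_t = 42.577e6,
                               alpha_ppm_per_c = -0.01) {
  check_scalar(b0_t, "b0_t", positive = TRUE)
  check_scalar(te_s, "te_s", positive = TRUE)
  check_scalar(frame_interval_s, "frame_interval_s", positive = TRUE)
  check_scalar(gamma_hz_per_t, "gamma_hz_per_t", positive = TRUE)
  check_scalar(alpha_ppm_per_c, "alpha_ppm_per_c")
  if (alpha_ppm_per_c >= 0)
    stop("alpha_ppm_per_c must be negative for aqueous tissue")
  structure(list(b0_t = b0_t, te_s = te_s, frame_interval_s = frame_interval_s,
                 gamma_hz_per_t = gamma_hz_per_t,
                 alpha_ppm_per_c = alpha_ppm_per_c),
            class = "acquisition_params")
}

#' PRF phase-per-degree coefficient (rad/degC)
#'
#' `2 pi gamma alpha 1e-6 B0 TE`; negative, since alpha < 0.
#'
#' @param params [acquisition_params()]
#' @export
prf_coefficient <- function(params) {
  2 * pi * params$gamma_hz_per_t * params$alpha_ppm_per_c * 1e-6 *
    params$b0_t * params$te_s
}

#' Largest per-step temperature change trackable without phase wrapping (degC)
#' @param params [acquisition_params()]
#' @export
wrap_limit_c <- function(params) pi / abs(prf_coefficient(params))

#' Complex image frame
#'
#' A single complex-valued image dynamic. Magnitude and phase are accessed via
#' `Mod(frame$data)` and `Arg(frame$data)`.
#'
#' @param data complex (or numeric) array
#' @param frame_index dynamic number (0-based count, informational)
#' @return object of class `complex_image_frame`
#' @export
complex_image_frame <- function(data, frame_index = 0L) {
  data <- as_spatial_array(data)
  storage.mode(data) <- "complex"
  if (any(!is.finite(data))) stop("complex image data must be finite")
  structure(list(data = data, frame_index = as.integer(frame_index)),
            class = "complex_image_frame")
}

#' Temperature change to phase increment
#'
#' `dPhi = 2 pi gamma alpha 1e-6 B0 TE dT` voxel-wise (radians). Heating
#' lowers the phase (alpha < 0).
#'
#' @param delta_t_step temperature change (degC), array
#' @param params [acquisition_params()]
#' @return phase increment (radians), same shape
#' @export
temp_to_phase_increment <- function(delta_t_step, params) {
  if (any(!is.finite(delta_t_step))) stop("temperature field must be finite")
  prf_coefficient(params) * delta_t_step
}

#' Phase difference to temperature change
#'
#' Inverse of [temp_to_phase_increment()]: the per-voxel phase difference is
#' wrapped into (-pi, pi] and divided by the PRF coefficient. Warns when any
#' voxel's wrapped difference is within 5% of pi (wrap risk: per-step
#' temperature changes beyond [wrap_limit_c()] alias).
#'
#' @param phase_n phase at the current dynamic (radians), array
#' @param phase_ref reference phase (radians), same grid
#' @param params [acquisition_params()]
#' @return temperature change (degC)
#' @export
phase_to_temp <- function(phase_n, phase_ref, params) {
  phase_n <- as_spatial_array(phase_n)
  phase_ref <- as_spatial_array(phase_ref)
  if (!same_dims(phase_n, phase_ref)) stop("phase grids must match")
  d <- wrap_phase(phase_n - phase_ref)
  if (max(abs(d)) > 0.95 * pi)
    warning("per-step phase difference within 5% of pi: temperature wrap risk")
  d / prf_coefficient(params)
}

#' Predict the next complex frame from a modeled temperature step
#'
#' The model-predicted frame reuses the current magnitude image unchanged and
#' advances the phase by the PRF increment of the predicted temperature step.
#'
#' @param acquired_frame [complex_image_frame()] at dynamic n
#' @param delta_t_step predicted temperature change between dynamics n and
#'   n+1 (degC)
#' @param params [acquisition_params()]
#' @return [complex_image_frame()] at dynamic n+1
#' @export
predict_complex_frame <- function(acquired_frame, delta_t_step, params) {
  if (!inherits(acquired_frame, "complex_image_frame"))
    stop("acquired_frame must be a complex_image_frame")
  delta_t_step <- as_spatial_array(delta_t_step)
  if (!same_dims(acquired_frame$data, delta_t_step))
    stop("temperature step must match the image grid")
  mag <- Mod(acquired_frame$data)
  ph <- wrap_phase(Arg(acquired_frame$data) +
                     temp_to_phase_increment(delta_t_step, params))
  complex_image_frame(mag * exp(1i * ph), acquired_frame$frame_index + 1L)
}

# Voxels with (numerically) no signal in either frame: phase is undefined
# there, so the temperature update is suppressed. The relative tolerance sits
# many orders of magnitude below any physical noise floor; it only masks the
# Arg() of floating-point dust at exactly-zero background voxels of synthetic
# data after FFT round trips.
no_signal_mask <- function(cur_data, next_data, rel_tol = 1e-6) {
  m1 <- Mod(cur_data); m2 <- Mod(next_data)
  m1 < rel_tol * max(m1) | m2 < rel_tol * max(m2)
}

#' Direct PRF reconstruction of fully sampled complex frames
#'
#' Accumulates per-frame wrapped phase differences (each step wrapped
#' independently, so heatings beyond the single-step wrap limit remain
#' trackable) into a temperature-change series relative to frame 1. Voxels
#' with numerically zero magnitude in either frame of a step carry no phase
#' information and contribute no update.
#'
#' @param frames list of [complex_image_frame()] (frame 1 = baseline)
#' @param params [acquisition_params()]
#' @param spacing_mm voxel spacing (mm)
#' @return a [temperature_series()]
#' @export
prf_reconstruct <- function(frames, params, spacing_mm) {
  if (length(frames) < 1L) stop("need at least one frame")
  dims <- dim(frames[[1L]]$data)
  nt <- length(frames)
  out <- array(0, dim = c(dims, nt))
  nvox <- prod(dims)
  acc <- array(0, dim = dims)
  prev <- frames[[1L]]$data
  coef <- prf_coefficient(params)
  for (n in seq_len(nt)[-1L]) {
    cur <- frames[[n]]$data
    step <- wrap_phase(Arg(cur) - Arg(prev)) / coef
    step[no_signal_mask(prev, cur)] <- 0
    acc <- acc + step
    prev <- cur
    out[(n - 1L) * nvox + seq_len(nvox)] <- acc
  }
  temperature_series(out, spacing_mm, params$frame_interval_s)
}
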