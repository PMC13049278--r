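# Shared small fixtures for the unit tests. Kept tiny so every file runs in
# seconds; the scaled-down study replications live in test-acceptance.R.

small_acq <- function() acquisition_params(b0_t = 3, te_s = 0.012,
                                           frame_interval_s = 4.5)

small_phantom <- function(dims = c(32L, 32L), spacing_mm = 2) {
  phantom_spec(dims, spacing_mm, baseline_magnitude = 100,
               props = brain_properties())
}

small_experiment <- function(noise_sd = 0, seed = 1, n_frames = 6,
                             dims = c(32L, 32L), peak = 3e6) {
  ph <- small_phantom(dims)
  nd <- length(dims)
  laser <- laser_spec(peak, orientation = c(rep(0, nd - 1L), 1))
  schedule <- power_schedule(45, 4, calibration_power_w = 4)
  sim <- simulate_experiment(ph, laser, schedule, small_acq(),
                             noise = list(complex_noise_sd = noise_sd,
                                          seed = seed),
                             n_frames = n_frames)
  list(phantom = ph, laser = laser, schedule = schedule, acq = small_acq(),
       sim = sim)
}

# A smooth positive Gaussian-bump source on the grid, in W/m^3.
gaussian_q <- function(dims, spacing_mm, peak = 1e6, sigma_mm = 6) {
  nd <- length(dims)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, nd)
  r2 <- array(0, dim = dims)
  for (ax in seq_len(nd)) {
    x <- (seq_len(dims[ax]) - 1 - (dims[ax] - 1) / 2) * spacing_mm[ax]
    r2 <- r2 + (x^2)[slice.index(r2, ax)]
  }
  peak * exp(-r2 / (2 * sigma_mm^2))
}
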