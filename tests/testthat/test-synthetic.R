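# Digital phantom generator: geometry, capsule source, noise calibration.

test_that("phantom ellipsoid occupies the grid and rejects small objects", {
  ph <- small_phantom(c(32L, 32L))
  expect_gt(mean(ph$object_mask), 0.5)
  expect_true(ph$object_mask[16, 16])
  expect_false(ph$object_mask[1, 1])
  expect_error(phantom_spec(c(32L, 32L), 2, object_semiaxes_frac = 0.5),
               "50%")
})

test_that("capsule Q matches a hand-computed point-to-segment distance", {
  ph <- small_phantom(c(33L, 33L), 2)          # odd grid: voxel 17 at 0 mm
  laser <- laser_spec(1e6, orientation = c(0, 1), emitting_length_mm = 10,
                      radial_decay_length_mm = 3)
  q <- make_laser_q(laser, ph)
  # on the segment midpoint: distance 0 -> peak
  expect_equal(q$values[17, 17], 1e6, tolerance = 1e-10)
  # voxel at (0 mm, +8 mm): 3 mm beyond the +5 mm segment end
  expect_equal(q$values[17, 21], 1e6 * exp(-3 / 3), tolerance = 1e-10)
  # voxel at (+6 mm, +2 mm): radial distance 6 mm from the axis
  expect_equal(q$values[20, 18], 1e6 * exp(-6 / 3), tolerance = 1e-10)
  # zero outside the object
  expect_true(all(q$values[!ph$object_mask] == 0))
})

test_that("the emitting segment must fit inside the object", {
  ph <- small_phantom(c(32L, 32L))
  laser <- laser_spec(1e6, tip_position_mm = c(30, 0), orientation = c(1, 0))
  expect_error(make_laser_q(laser, ph), "inside")
})

test_that("simulate_experiment is deterministic in its seed", {
  a <- small_experiment(noise_sd = 1, seed = 31, n_frames = 3)$sim
  b <- small_experiment(noise_sd = 1, seed = 31, n_frames = 3)$sim
  c <- small_experiment(noise_sd = 1, seed = 32, n_frames = 3)$sim
  expect_identical(a$frames[[3]]$data, b$frames[[3]]$data)
  expect_false(identical(a$frames[[3]]$data, c$frames[[3]]$data))
  expect_identical(a$truth$frames, c$truth$frames)   # truth is noise-free
})

test_that("noise_sd_for_precision closes the loop at the study levels", {
  # zero-power heating: the measured background precision of the PRF
  # reconstruction must recover the requested value within 10%
  for (case in list(list(acq = small_acq(), target = 0.2),
                    list(acq = acquisition_params(1.5, 0.015, 6.4),
                         target = 0.7))) {
    ph <- small_phantom(c(32L, 32L))
    laser <- laser_spec(3e6, orientation = c(0, 1))
    sched <- power_schedule(10, 0, calibration_power_w = 4)
    sim <- simulate_experiment(ph, laser, sched, case$acq,
                               noise = list(target_temp_precision_c = case$target,
                                            seed = 41),
                               n_frames = 40)
    rec <- prf_reconstruct(sim$frames, case$acq, ph$spacing_mm)
    roi <- array(FALSE, dim = ph$dims); roi[12:20, 12:20] <- TRUE
    pa <- background_precision_accuracy(rec, roi)
    expect_equal(pa$precision_c, case$target, tolerance = 0.1)
  }
})

test_that("noise spec requires exactly one noise parameterization", {
  ph <- small_phantom(c(16L, 16L))
  laser <- laser_spec(3e6, orientation = c(0, 1))
  sched <- power_schedule(10, 4, calibration_power_w = 4)
  expect_error(simulate_experiment(ph, laser, sched, small_acq(),
                                   noise = list(seed = 1), 2),
               "exactly one")
  expect_error(simulate_experiment(ph, laser, sched, small_acq(),
                                   noise = list(target_temp_precision_c = 0.2,
                                                complex_noise_sd = 1,
                                                seed = 1), 2),
               "exactly one")
})

test_that("perturb_model scales copies and leaves the originals untouched", {
  q <- qmap(gaussian_q(c(8L, 8L), 2), 2)
  props <- brain_properties()
  p <- perturb_model(q, kappa_error = 0.5, q_error = -0.2, props)
  expect_equal(p$q$values, q$values * 0.8)
  expect_equal(p$props$conductivity_w_m_c, 0.51 * 1.5)
  expect_equal(q$values[4, 4], gaussian_q(c(8L, 8L), 2)[4, 4])
  expect_equal(props$conductivity_w_m_c, 0.51)
  expect_error(perturb_model(q, -1.5, 0, props), "> -1")
})
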