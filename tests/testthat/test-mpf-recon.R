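# Model predictive filtering reconstruction.

test_that("R = 1 MPF equals the direct reconstruction to 1e-10 degC", {
  ex <- small_experiment(noise_sd = 0.5, seed = 21, n_frames = 6)
  direct <- prf_reconstruct(ex$sim$frames, ex$acq, ex$phantom$spacing_mm)
  cfg <- mpf_config(ex$phantom$props, ex$acq, ex$sim$q, ex$schedule)
  res <- mpf_reconstruct(ex$sim$kspace, cfg)
  expect_lt(max(abs(res$temperature$frames - direct$frames)), 1e-10)
  expect_true(all(res$diagnostics$model_fraction == 0))
})

test_that("noise-free self-consistent model recovers exactly at R = 2..5", {
  dims <- c(60L, 60L)
  ph <- phantom_spec(dims, 2, props = brain_properties())
  laser <- laser_spec(3e6, orientation = c(0, 1))
  sched <- power_schedule(45, 4, calibration_power_w = 4)
  acq <- small_acq()
  sim <- simulate_experiment(ph, laser, sched, acq,
                             noise = list(complex_noise_sd = 0, seed = 1),
                             n_frames = 6)
  direct <- prf_reconstruct(sim$frames, acq, ph$spacing_mm)
  cfg <- mpf_config(ph$props, acq, sim$q, sched)
  for (R in 2:5) {
    sub <- sim$kspace
    for (n in seq_along(sub)[-1L])
      sub[[n]] <- subsample_kspace(sub[[n]], epi_mask(60L, R, n - 2L))
    res <- mpf_reconstruct(sub, cfg)
    expect_lt(max(abs(res$temperature$frames - direct$frames)), 1e-4)
    expect_equal(res$diagnostics$model_fraction[-1], rep(1 - 1 / R, 5),
                 tolerance = 1e-12)
  }
})

test_that("acquired lines stay bit-exact (data consistency enforced)", {
  ex <- small_experiment(noise_sd = 0.5, seed = 22, n_frames = 5)
  cfg <- mpf_config(ex$phantom$props, ex$acq, ex$sim$q, ex$schedule,
                    data_consistency_check = TRUE)
  sub <- ex$sim$kspace
  for (n in seq_along(sub)[-1L])
    sub[[n]] <- subsample_kspace(sub[[n]], epi_mask(32L, 2L, n - 2L))
  expect_no_error(mpf_reconstruct(sub, cfg))
})

test_that("MPF corrects model error that pure prediction accumulates", {
  dims <- c(40L, 40L)
  ph <- phantom_spec(dims, 2, props = brain_properties())
  laser <- laser_spec(3e6, orientation = c(0, 1))
  sched <- power_schedule(45, 4, calibration_power_w = 4)
  acq <- small_acq()
  sim <- simulate_experiment(ph, laser, sched, acq,
                             noise = list(complex_noise_sd = 0, seed = 2),
                             n_frames = 8)
  # feed the reconstruction a deliberately wrong model (+30% Q, +30% kappa)
  pert <- perturb_model(sim$q, kappa_error = 0.3, q_error = 0.3, ph$props)
  cfg <- mpf_config(pert$props, acq, pert$q, sched)
  sub <- sim$kspace
  for (n in seq_along(sub)[-1L])
    sub[[n]] <- subsample_kspace(sub[[n]], epi_mask(40L, 2L, n - 2L))
  res <- mpf_reconstruct(sub, cfg)
  truth <- prf_reconstruct(sim$frames, acq, ph$spacing_mm)
  # monitor the true hottest voxel (a global max would be contaminated by
  # zero-magnitude background voxels whose phase is meaningless)
  v <- arrayInd(which.max(get_frame(truth, 8)), dims)[1, ]
  curve_at <- function(ser) vapply(1:8, function(i) get_frame(ser, i)[v[1], v[2]], 0)
  mpf_err <- max(abs(curve_at(res$temperature) - curve_at(truth)))
  # pure model rollout with the same wrong parameters, no data
  rollout <- simulate_heating(0, pert$q, pert$props, sched,
                              acq$frame_interval_s, 8)
  model_err <- max(abs(curve_at(rollout) - curve_at(truth)))
  expect_lt(mpf_err, 0.5 * model_err)
  expect_gt(model_err, 0.5)                    # the perturbation really bites
})

test_that("zero heating stays zero through subsampled MPF (noise-free)", {
  dims <- c(32L, 32L)
  ph <- phantom_spec(dims, 2, props = brain_properties())
  laser <- laser_spec(3e6, orientation = c(0, 1))
  sched <- power_schedule(45, 0, calibration_power_w = 4)   # laser never on
  acq <- small_acq()
  sim <- simulate_experiment(ph, laser, sched, acq,
                             noise = list(complex_noise_sd = 0, seed = 3),
                             n_frames = 5)
  cfg <- mpf_config(ph$props, acq, sim$q, sched)
  sub <- sim$kspace
  for (n in seq_along(sub)[-1L])
    sub[[n]] <- subsample_kspace(sub[[n]], epi_mask(32L, 2L, n - 2L))
  res <- mpf_reconstruct(sub, cfg)
  expect_lt(max(abs(res$temperature$frames)), 1e-9)
})

test_that("mpf_reconstruct validates its inputs", {
  ex <- small_experiment(n_frames = 3)
  cfg <- mpf_config(ex$phantom$props, ex$acq, ex$sim$q, ex$schedule)
  expect_error(mpf_reconstruct(list(), cfg), "baseline")
  k <- ex$sim$kspace
  k[[1L]] <- subsample_kspace(k[[1L]], epi_mask(32L, 2L, 0L))
  expect_error(mpf_reconstruct(k, cfg), "fully sampled")
  # Q grid mismatch
  bad_q <- qmap(gaussian_q(c(16L, 16L), 2), 2)
  cfg2 <- mpf_config(ex$phantom$props, ex$acq, bad_q, ex$schedule)
  expect_error(mpf_reconstruct(ex$sim$kspace, cfg2), "grid")
})
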