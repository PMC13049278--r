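# Forward bioheat model: k-grid, propagator, spectral stepper, schedules.

test_that("build_k_grid places DC at index 1 with symmetric frequencies", {
  # 4 samples at 1 m spacing: frequencies 0, 0.25, 0.5, -0.25 cycles/m
  kg <- build_k_grid(4L, 1000)
  expect_equal(as.numeric(kg), c(0, 0.25, 0.5, 0.25))
  kg2 <- build_k_grid(c(4L, 4L), 1000)
  expect_equal(kg2[1, 1], 0)
  expect_equal(kg2[3, 3], sqrt(0.5^2 + 0.5^2))
  expect_equal(kg2[2, 1], kg2[4, 1])   # symmetric under negation
})

test_that("heat propagator decays within (0, 1] and is 1 at DC", {
  kg <- build_k_grid(c(16L, 16L), 2)
  hp <- heat_propagator(kg, kappa_m2_s = 1.3e-7, t_s = 10)
  expect_true(all(hp$decay > 0 & hp$decay <= 1))
  expect_equal(hp$decay[1, 1], 1)
  # perfusion damps every mode including DC
  hp_w <- heat_propagator(kg, 1.3e-7, 10, w_over_rho_per_s = 0.01)
  expect_equal(hp_w$decay[1, 1], exp(-0.1))
  expect_true(all(hp_w$decay < hp$decay + 1e-15))
})

test_that("single Fourier mode decays at the analytic rate", {
  n <- 32L; sp <- 2
  props <- brain_properties()
  x <- (seq_len(n) - 1) / n
  field <- outer(cos(2 * pi * x), rep(1, n))
  dt <- 5
  stepped <- step_temperature(field, array(0, dim = c(n, n)), props,
                              power_scale = 1, dt_s = dt, spacing_mm = sp)
  L_m <- n * sp / 1000
  expected <- field * exp(-4 * pi^2 * thermal_diffusivity(props) * dt / L_m^2)
  expect_equal(stepped, expected, tolerance = 1e-12)
})

test_that("spectral step conserves the mean without perfusion or source", {
  set.seed(11)
  f <- array(rnorm(16^2), dim = c(16L, 16L))
  out <- step_temperature(f, array(0, dim = c(16L, 16L)), brain_properties(),
                          1, 10, spacing_mm = 2)
  expect_equal(mean(out), mean(f), tolerance = 1e-12)
})

test_that("stepper is linear in temperature and source", {
  set.seed(12)
  f <- array(rnorm(16^2), dim = c(16L, 16L))
  q <- gaussian_q(c(16L, 16L), 2)
  props <- brain_properties()
  a1 <- step_temperature(3 * f, 3 * q, props, 1, 4.5, spacing_mm = 2)
  a2 <- step_temperature(f, q, props, 1, 4.5, spacing_mm = 2)
  expect_equal(a1, 3 * a2, tolerance = 1e-10)
})

test_that("uniform source heats uniformly at Q dt / (rho c) without diffusion loss", {
  props <- brain_properties()
  q <- array(1e5, dim = c(8L, 8L))
  out <- step_temperature(array(0, dim = c(8L, 8L)), q, props, 1, 10,
                          spacing_mm = 2)
  rho_c <- props$density_kg_m3 * props$specific_heat_j_kg_c
  expect_equal(out, array(1e5 * 10 / rho_c, dim = c(8L, 8L)), tolerance = 1e-12)
})

test_that("spectral stepper agrees with the finite-difference oracle", {
  dims <- c(16L, 16L, 8L); sp <- c(2, 2, 3)
  props <- gellan_gum_properties()
  q <- gaussian_q(dims, sp, peak = 2e6)
  dt <- 0.25; nstep <- 40L                    # 10 s of heating
  fd <- array(0, dim = dims)
  for (i in seq_len(nstep))
    fd <- fd_reference_step(fd, q, props, 1, dt, spacing_mm = sp)
  spec <- array(0, dim = dims)
  for (i in seq_len(nstep))
    spec <- step_temperature(spec, q, props, 1, dt, spacing_mm = sp)
  expect_lt(max(abs(spec - fd)) / max(spec), 0.01)
})

test_that("fd_reference_step enforces its stability bound", {
  q <- array(0, dim = c(8L, 8L))
  expect_error(fd_reference_step(q, q, brain_properties(), 1, 100,
                                 spacing_mm = 1),
               "stability")
})

test_that("power schedules: lookup, breaks, and sub-stepping", {
  s <- power_schedule(c(10, 20), c(4, 8), calibration_power_w = 4)
  expect_equal(power_at(s, c(0, 5, 10, 10.1, 30, 31)), c(4, 4, 4, 8, 8, 0))
  ss <- mpftherm:::substeps_for_interval(s, 5, 25)
  expect_equal(ss$dt, c(5, 15))
  expect_equal(ss$power_w, c(4, 8))
  # zero-length outside: after schedule end the power is zero
  ss2 <- mpftherm:::substeps_for_interval(s, 30, 40)
  expect_equal(ss2$power_w, 0)
  expect_error(power_schedule(c(10, -1), c(4, 4), 4), "positive")
  expect_error(power_schedule(10, -4, 4), ">= 0")
})

test_that("simulate_heating reports baseline first and heats monotonically", {
  dims <- c(16L, 16L)
  q <- gaussian_q(dims, 2, peak = 2e6)
  ser <- simulate_heating(0, q, brain_properties(),
                          constant_schedule(4, 100), 4.5, 6, spacing_mm = 2)
  expect_s3_class(ser, "temperature_series")
  expect_equal(n_frames(ser), 6L)
  expect_equal(get_frame(ser, 1), array(0, dim = dims))
  hot <- hottest_curve(ser)
  expect_true(all(diff(hot) > 0))             # power on throughout
})

test_that("heating decays after laser off", {
  dims <- c(16L, 16L)
  q <- gaussian_q(dims, 2, peak = 2e6)
  ser <- simulate_heating(0, q, brain_properties(),
                          constant_schedule(4, 9), 4.5, 8, spacing_mm = 2)
  hot <- hottest_curve(ser)
  expect_true(all(diff(hot[3:8]) < 0))        # off from 9 s onward
})

test_that("tissue properties derive diffusivity and validate inputs", {
  p <- gellan_gum_properties()
  expect_equal(thermal_diffusivity(p), 0.56 / (1030 * 4186))
  expect_error(tissue_properties(-1, 4186, 0.56), "> 0")
  expect_error(tissue_properties(1030, 4186, 0.56, perfusion_kg_m3_s = -2),
               ">= 0")
})
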