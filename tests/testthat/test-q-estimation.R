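# Green's-function SAR/Q estimation and the refine pipeline.

test_that("estimate_sar exactly inverts one forward frame", {
  dims <- c(24L, 24L); sp <- 2
  props <- gellan_gum_properties()
  q <- gaussian_q(dims, sp, peak = 2e6)
  ser <- simulate_heating(0, q, props, constant_schedule(4, 10), 4.5, 2,
                          spacing_mm = sp)
  sar <- estimate_sar(get_frame(ser, 2), 4.5, props, sp)
  expect_equal(sar * props$density_kg_m3, q, tolerance = 1e-8)
})

test_that("estimate_sar maps a uniform offset to c * mean / t (DC limit)", {
  props <- brain_properties()
  dT <- array(2, dim = c(8L, 8L))
  sar <- estimate_sar(dT, 10, props, 2)
  expect_equal(sar, array(props$specific_heat_j_kg_c * 2 / 10, dim = c(8L, 8L)),
               tolerance = 1e-10)
})

test_that("estimate_sar is linear in the temperature field", {
  set.seed(3)
  dT <- gaussian_q(c(16L, 16L), 2, peak = 2)
  s1 <- estimate_sar(3 * dT, 5, brain_properties(), 2)
  s2 <- estimate_sar(dT, 5, brain_properties(), 2)
  expect_equal(s1, 3 * s2, tolerance = 1e-10)
})

test_that("sar_to_q multiplies by density", {
  sar <- gaussian_q(c(8L, 8L), 2, peak = 10)
  q <- sar_to_q(sar, brain_properties(), 2)
  expect_s3_class(q, "qmap")
  expect_equal(q$values, sar * 1046)
  q2 <- sar_to_q(sar, 1000, 2)
  expect_equal(q2$values, sar * 1000)
})

test_that("median_filter_box matches a naive per-voxel median with reflection", {
  set.seed(4)
  x <- array(rnorm(7 * 6), dim = c(7L, 6L))
  got <- median_filter_box(x, 3L)
  ref <- array(0, dim = dim(x))
  # symmetric reflection including the edge sample: 0 -> 1, n+1 -> n
  reflect <- function(i, n) ifelse(i < 1L, 1L - i, ifelse(i > n, 2L * n + 1L - i, i))
  for (i in 1:7) for (j in 1:6) {
    vals <- c()
    for (di in -1:1) for (dj in -1:1)
      vals <- c(vals, x[reflect(i + di, 7L), reflect(j + dj, 6L)])
    ref[i, j] <- stats::median(vals)
  }
  expect_equal(got, ref)
})

test_that("median filter preserves constants and suppresses salt noise", {
  x <- array(5, dim = c(6L, 6L, 4L))
  expect_equal(median_filter_box(x, 3L), x)
  x[3, 3, 2] <- 1000
  expect_equal(median_filter_box(x, 3L), array(5, dim = dim(x)))
  expect_error(median_filter_box(x, 2L), "odd")
})

test_that("default_crop_roi hugs the main lobe and ignores distant outliers", {
  q <- gaussian_q(c(48L, 48L), 2, peak = 1, sigma_mm = 4)
  q[2, 2] <- 0.5                               # isolated supra-threshold noise
  roi <- default_crop_roi(q, threshold_frac = 0.05, dilate_voxels = 0L)
  # 5% contour of the bump: r = sigma*sqrt(2 ln 20) ~ 9.8 mm ~ 5 voxels
  expect_true(all(roi$lo >= 19) && all(roi$hi <= 30))
  # global-bounding-box behaviour would have included voxel (2,2)
  expect_true(all(roi$lo > 2))
})

test_that("refine_q output is invariant to pre-scaling of the raw map", {
  dims <- c(24L, 24L); sp <- 2
  props <- gellan_gum_properties()
  sched <- constant_schedule(4, 10)
  q_true <- gaussian_q(dims, sp, peak = 2e6)
  ser <- simulate_heating(0, q_true, props, sched, 4.5, 3, spacing_mm = sp)
  raw1 <- qmap(q_true, sp)
  raw5 <- qmap(q_true * 5, sp)
  r1 <- refine_q(raw1, ser, props, sched)
  r5 <- refine_q(raw5, ser, props, sched)
  expect_equal(r1$values, r5$values, tolerance = 1e-9)
  expect_equal(r5$provenance$scale_factor, r1$provenance$scale_factor / 5,
               tolerance = 1e-9)
})

test_that("refine_q zeroes outside the crop box and records it", {
  dims <- c(24L, 24L); sp <- 2
  props <- gellan_gum_properties()
  sched <- constant_schedule(4, 10)
  q_true <- gaussian_q(dims, sp, peak = 2e6, sigma_mm = 4)
  ser <- simulate_heating(0, q_true, props, sched, 4.5, 3, spacing_mm = sp)
  roi <- list(lo = c(9L, 9L), hi = c(16L, 16L))
  r <- refine_q(qmap(q_true, sp), ser, props, sched, crop_roi = roi)
  expect_equal(r$crop_roi, roi)
  outside <- r$values
  outside[9:16, 9:16] <- 0
  expect_true(all(outside == 0))
  expect_true(any(r$values != 0))
})

test_that("estimate_q round trip reproduces the heating (noise-free, 2D)", {
  dims <- c(32L, 32L); sp <- 2
  props <- gellan_gum_properties()
  sched <- constant_schedule(4, 60)
  q_true <- gaussian_q(dims, sp, peak = 2e6, sigma_mm = 5)
  ser <- simulate_heating(0, q_true, props, sched, 4.5, 6, spacing_mm = sp)
  h1 <- hottest_curve(ser)
  # without the median filter the deconvolve/scale/crop chain is essentially
  # an exact inverse (crop tails are negligible)
  q_exact <- estimate_q(ser, props, sched, dynamic_index = 1L,
                        median_filter = FALSE)
  h_exact <- hottest_curve(simulate_heating(0, q_exact, props, sched, 4.5, 6))
  expect_lt(max(abs(h_exact[-1] - h1[-1]) / h1[-1]), 1e-6)
  # the median filter broadens the peak; the rescale pins the curve maximum,
  # leaving a bounded early-frame shape error
  q_filt <- estimate_q(ser, props, sched, dynamic_index = 1L)
  h_filt <- hottest_curve(simulate_heating(0, q_filt, props, sched, 4.5, 6))
  expect_equal(max(h_filt), max(h1), tolerance = 1e-6)
  expect_lt(max(abs(h_filt[-1] - h1[-1]) / h1[-1]), 0.05)
  expect_error(estimate_q(ser, props, sched, dynamic_index = 7L),
               "out of range")
})
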