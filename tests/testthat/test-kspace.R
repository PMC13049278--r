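# k-space conventions, sampling mask generators, filling, interpolation.

test_that("image <-> k-space is a unitary pair (Parseval, identity)", {
  set.seed(6)
  img <- complex_image_frame(array(complex(real = rnorm(16 * 12),
                                           imaginary = rnorm(16 * 12)),
                                   dim = c(16L, 12L)), 3L)
  k <- image_to_kspace(img)
  expect_equal(sum(Mod(k$values)^2), sum(Mod(img$data)^2), tolerance = 1e-10)
  back <- kspace_to_image(k)
  expect_equal(back$data, img$data, tolerance = 1e-12)
  expect_equal(back$frame_index, 3L)
})

test_that("k-space values are stored centered: constant image -> single center peak", {
  n <- 8L
  img <- complex_image_frame(array(1 + 0i, dim = c(n, n)))
  k <- image_to_kspace(img)
  expect_equal(Mod(k$values[n / 2 + 1, n / 2 + 1]), n, tolerance = 1e-12)
  off <- Mod(k$values); off[n / 2 + 1, n / 2 + 1] <- 0
  expect_lt(max(off), 1e-12)
})

test_that("sampling_mask validates the kept-line fraction", {
  expect_s3_class(sampling_mask(rep(c(TRUE, FALSE), 8), R = 2), "sampling_mask")
  expect_error(sampling_mask(rep(TRUE, 16), R = 2), "inconsistent")
  expect_error(sampling_mask(c(rep(TRUE, 15), FALSE), R = 1), "all lines")
})

test_that("epi_mask keeps 1/R of interleaved trains and rotates with frame", {
  n_tr <- 24L; tl <- 4L
  for (R in c(2L, 3L, 4L)) {
    m <- epi_mask(n_tr, R, frame_index = 0L, train_length = tl)
    expect_equal(sum(m$pattern), n_tr * tl / R)
    # union over R consecutive frames covers every line exactly once
    acc <- rep(0L, n_tr * tl)
    for (f in seq_len(R) - 1L)
      acc <- acc + epi_mask(n_tr, R, f, tl)$pattern
    expect_true(all(acc == 1L))
  }
  expect_error(epi_mask(24L, 5L), "divisible")
})

test_that("interleaved epi trains subsample k-space evenly (uniform stride)", {
  m <- epi_mask(24L, 2L, frame_index = 0L, train_length = 4L)
  kept <- which(m$pattern)
  expect_true(all(diff(kept) == 2L))           # stride R, no blocky gaps
  m3 <- epi_mask(24L, 3L, frame_index = 1L, train_length = 4L)
  expect_true(all(diff(which(m3$pattern)) == 3L))
})

test_that("gaussian_mask always keeps the central block and meets its quota", {
  n <- 256L
  m <- gaussian_mask(n, 3L, center_width = 20L, seed = 9)
  expect_equal(sum(m$pattern), round(n / 3))
  # central 20 lines around the (0-based) center 128: 1-based 119..138
  expect_true(all(m$pattern[119:138]))
  # reproducible under the same seed, different under another
  expect_identical(gaussian_mask(n, 3L, seed = 9)$pattern, m$pattern)
  expect_false(identical(gaussian_mask(n, 3L, seed = 10)$pattern, m$pattern))
  expect_error(gaussian_mask(64L, 8L, center_width = 20L), "at least")
})

test_that("gaussian_mask sampling density concentrates near the center", {
  n <- 256L
  hits <- rep(0, n)
  for (s in 1:40) hits <- hits + gaussian_mask(n, 3L, seed = s)$pattern
  inner <- mean(hits[97:160]) / 40              # +-32 lines around center
  outer <- mean(hits[c(1:32, 225:256)]) / 40
  expect_gt(inner, outer + 0.3)
})

test_that("with_local_seed leaves the caller's RNG stream untouched", {
  set.seed(42)
  r1 <- runif(1)
  set.seed(42)
  invisible(mpftherm:::with_local_seed(7, runif(5)))
  r2 <- runif(1)
  expect_identical(r1, r2)
})

test_that("subsampled frames carry NA lines and refuse direct inversion", {
  set.seed(8)
  img <- complex_image_frame(array(complex(real = rnorm(256),
                                           imaginary = rnorm(256)),
                                   dim = c(16L, 16L)))
  k <- image_to_kspace(img)
  m <- epi_mask(16L, 2L, 0L)
  sub <- subsample_kspace(k, m)
  expect_true(all(is.na(sub$values[, which(!m$pattern)])))
  expect_true(all(!is.na(sub$values[, which(m$pattern)])))
  expect_error(kspace_to_image(sub), "unacquired")
})

test_that("fill_missing is bit-exact on acquired lines, prediction elsewhere", {
  set.seed(9)
  mk <- function() complex_image_frame(array(complex(real = rnorm(256),
                                                     imaginary = rnorm(256)),
                                             dim = c(16L, 16L)))
  ka <- image_to_kspace(mk()); kp <- image_to_kspace(mk())
  m <- epi_mask(16L, 2L, 1L)
  sub <- subsample_kspace(ka, m)
  filled <- fill_missing(sub, kp)
  keep <- which(m$pattern)
  expect_identical(filled$values[, keep], ka$values[, keep])
  expect_identical(filled$values[, -keep], kp$values[, -keep])
  expect_true(mpftherm:::is_fully_sampled(filled))
})

test_that("zero_fill_interpolate preserves a constant image and energy scale", {
  img <- complex_image_frame(array(3 + 0i, dim = c(8L, 8L)))
  k <- image_to_kspace(img)
  up <- zero_fill_interpolate(k, c(16L, 16L))
  expect_equal(dim(up$data), c(16L, 16L))
  expect_equal(Mod(up$data), array(3, dim = c(16L, 16L)), tolerance = 1e-10)
  expect_error(zero_fill_interpolate(k, c(4L, 16L)), ">=")
})
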