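# Cartesian k-space handling: unitary FFT/IFFT pairing, retrospective
# subsampling mask generators (segmented-EPI kz-inside-ky and pseudo-random
# pseudo-Gaussian), data-consistent line filling, and zero-fill interpolation.
#
# Conventions (tested via Parseval): unitary scaling both directions;
# kspace_frame values are stored in centered order (DC at index n/2 + 1 per
# axis) so that mask line indices, the "middle 20 lines" of the Gaussian
# scheme, and zero-padding all read naturally; the wrap reordering happens
# inside the transform pair. Masks index phase-encode lines along `line_dim`
# (default 2: ky for both 2D and 3D arrays).

#' Per-frame sampling mask over phase-encode lines
#'
#' @param pattern logical vector, one entry per phase-encode line
#' @param R nominal reduction factor (>= 1); the fraction of TRUE lines must
#'   equal 1/R within one line's rounding
#' @param frame_index dynamic the mask belongs to (informational)
#' @param scheme generator name ("epi", "gaussian", "custom")
#' @return object of class `sampling_mask`
#' @export
sampling_mask <- function(pattern, R = 1, frame_index = 0L, scheme = "custom") {
  pattern <- as.logical(pattern)
  if (any(is.na(pattern))) stop("mask pattern must be TRUE/FALSE")
  check_scalar(R, "R", positive = TRUE)
  if (R == 1 && !all(pattern)) stop("R = 1 requires all lines acquired")
  n <- length(pattern)
  if (abs(sum(pattern) - n / R) > 1 + 1e-9)
    stop(sprintf("mask keeps %d of %d lines, inconsistent with R = %g",
                 sum(pattern), n, R))
  structure(list(pattern = pattern, R = R,
                 frame_index = as.integer(frame_index), scheme = scheme),
            class = "sampling_mask")
}

#' @export
print.sampling_mask <- function(x, ...) {
  cat(sprintf("Sampling mask (%s): %d/%d lines, R = %g, frame %d\n",
              x$scheme, sum(x$pattern), length(x$pattern), x$R, x$frame_index))
  invisible(x)
}

#' Cartesian k-space frame
#'
#' Complex spatial-frequency data in standard DFT order. Lines not covered by
#' `mask` hold `NA` and are never silently zero-filled; [kspace_to_image()]
#' refuses frames with missing lines.
#'
#' @param values complex array
#' @param mask [sampling_mask()] or NULL (fully sampled)
#' @param frame_index dynamic number (informational)
#' @param line_dim array dimension the mask indexes (default 2)
#' @return object of class `kspace_frame`
#' @export
kspace_frame <- function(values, mask = NULL, frame_index = 0L, line_dim = 2L) {
  values <- as_spatial_array(values)
  storage.mode(values) <- "complex"
  if (!is.null(mask)) {
    if (!inherits(mask, "sampling_mask")) stop("mask must be a sampling_mask")
    if (length(mask$pattern) != dim(values)[line_dim])
      stop("mask length must equal the number of phase-encode lines")
    acq <- index_lines(values, line_dim, which(mask$pattern))
    if (any(!is.finite(acq))) stop("acquired k-space lines must be finite")
  } else if (any(!is.finite(values))) {
    stop("fully sampled k-space must be finite")
  }
  structure(list(values = values, mask = mask,
                 frame_index = as.integer(frame_index),
                 line_dim = as.integer(line_dim)),
            class = "kspace_frame")
}

is_fully_sampled <- function(k) is.null(k$mask) || all(k$mask$pattern)

#' Unitary FFT of a complex image frame
#' @param frame [complex_image_frame()]
#' @param line_dim phase-encode dimension recorded on the result (default 2)
#' @return fully sampled [kspace_frame()]
#' @export
image_to_kspace <- function(frame, line_dim = 2L) {
  if (!inherits(frame, "complex_image_frame"))
    stop("frame must be a complex_image_frame")
  kspace_frame(fftshift(ufft(frame$data)), mask = NULL,
               frame_index = frame$frame_index, line_dim = line_dim)
}

#' Unitary inverse FFT of a fully sampled k-space frame
#' @param k [kspace_frame()]; must be fully sampled (or explicitly filled)
#' @return [complex_image_frame()]
#' @export
kspace_to_image <- function(k) {
  if (!inherits(k, "kspace_frame")) stop("k must be a kspace_frame")
  if (!is_fully_sampled(k))
    stop("k-space frame has unacquired lines; fill them first")
  complex_image_frame(uifft(ifftshift(k$values)), k$frame_index)
}

#' Segmented-EPI kz-inside-ky subsampling mask
#'
#' Keeps every R-th ky echo train (all kz lines of a kept train are acquired),
#' with the kept-train offset rotating as `frame_index mod R` so the model
#' supplements different k-space regions in consecutive dynamics. Unions over
#' R consecutive frames cover all trains exactly once. Echo trains are
#' interleaved across ky in the usual segmented-EPI fashion (train t acquires
#' lines t, t + n_trains, t + 2 n_trains, ...), so keeping every R-th train
#' subsamples k-space evenly.
#'
#' @param n_ky_trains number of ky echo trains
#' @param R integer reduction factor (>= 1, <= n_ky_trains)
#' @param frame_index dynamic number (sets the rotation offset)
#' @param train_length phase-encode lines per train (echo train length,
#'   default 1); the returned pattern has `n_ky_trains * train_length` entries
#' @return [sampling_mask()]
#' @export
epi_mask <- function(n_ky_trains, R, frame_index = 0L, train_length = 1L) {
  if (R < 1 || R != round(R)) stop("R must be a positive integer")
  if (R > n_ky_trains) stop("R must not exceed the number of ky trains")
  if (n_ky_trains %% R != 0)
    stop("n_ky_trains must be divisible by R for stride sampling")
  line0 <- seq_len(n_ky_trains * train_length) - 1L   # 0-based line index
  train <- line0 %% n_ky_trains                       # interleaved trains
  pattern <- (train - frame_index) %% R == 0
  sampling_mask(pattern, R = R, frame_index = frame_index, scheme = "epi")
}

#' Pseudo-random pseudo-Gaussian subsampling mask
#'
#' The central `center_width` lines are always acquired (fully sampled
#' k-space center); the remaining quota of `round(n_lines / R) -
#' center_width` lines is drawn without replacement with probability
#' proportional to a normal density centered on the k-space center. Masks are
#' drawn independently per frame so model supplementation is incoherent over
#' time.
#'
#' @param n_lines total phase-encode lines
#' @param R reduction factor
#' @param center_width always-acquired central block (default 20); with
#'   0-based line indices the block is lines `n/2 - center_width/2` ...
#'   `n/2 + center_width/2 - 1`
#' @param seed optional integer; when given, the draw is made reproducible
#'   without disturbing the caller's RNG stream
#' @param frame_index dynamic number (informational)
#' @param sd_lines standard deviation of the sampling density in lines
#'   (default `n_lines / 6`, so +-3 sigma spans k-space)
#' @return [sampling_mask()] in image line order (line 1 = lowest ky index;
#'   the k-space center line is `n_lines/2 + 1`, matching DC after
#'   [fftshift()])
#' @export
gaussian_mask <- function(n_lines, R, center_width = 20L, seed = NULL,
                          frame_index = 0L, sd_lines = n_lines / 6) {
  check_scalar(R, "R", positive = TRUE)
  n_keep <- round(n_lines / R)
  if (n_keep < center_width)
    stop("line quota n_lines/R must be at least center_width")
  center0 <- n_lines %/% 2L                       # 0-based center line
  block <- (center0 - center_width %/% 2L):(center0 + (center_width + 1L) %/% 2L - 1L)
  pattern <- rep(FALSE, n_lines)
  pattern[block + 1L] <- TRUE
  extra <- n_keep - center_width
  if (extra > 0L) {
    candidates <- setdiff(seq_len(n_lines) - 1L, block)
    prob <- stats::dnorm(candidates, mean = center0, sd = sd_lines)
    draw <- function() sample(candidates, extra, replace = FALSE, prob = prob)
    chosen <- if (is.null(seed)) draw() else with_local_seed(seed, draw())
    pattern[chosen + 1L] <- TRUE
  }
  sampling_mask(pattern, R = R, frame_index = frame_index, scheme = "gaussian")
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's stream.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Retrospectively subsample a fully sampled k-space frame
#'
#' Unacquired lines are set to `NA` (flagged, not zero-filled) and the mask is
#' attached to the frame.
#'
#' @param k fully sampled [kspace_frame()]
#' @param mask [sampling_mask()]
#' @return subsampled [kspace_frame()]
#' @export
subsample_kspace <- function(k, mask) {
  if (!inherits(k, "kspace_frame")) stop("k must be a kspace_frame")
  if (!inherits(mask, "sampling_mask")) stop("mask must be a sampling_mask")
  if (length(mask$pattern) != dim(k$values)[k$line_dim])
    stop("mask length must equal the number of phase-encode lines")
  v <- assign_lines(k$values, k$line_dim, which(!mask$pattern), NA_complex_)
  structure(list(values = v, mask = mask, frame_index = k$frame_index,
                 line_dim = k$line_dim), class = "kspace_frame")
}

#' Fill unacquired k-space lines from a model-predicted frame
#'
#' Output equals the acquired data bit-exactly on acquired lines and the
#' prediction elsewhere; the result is fully sampled.
#'
#' @param acquired subsampled [kspace_frame()] with mask
#' @param predicted fully sampled [kspace_frame()] on the same grid
#' @return fully sampled [kspace_frame()]
#' @export
fill_missing <- function(acquired, predicted) {
  if (!inherits(acquired, "kspace_frame") || !inherits(predicted, "kspace_frame"))
    stop("both arguments must be kspace_frame objects")
  if (!same_dims(acquired$values, predicted$values))
    stop("acquired and predicted grids must match")
  if (!is_fully_sampled(predicted))
    stop("predicted frame must be fully sampled")
  if (is.null(acquired$mask)) return(kspace_frame(acquired$values, NULL,
                                                  acquired$frame_index,
                                                  acquired$line_dim))
  v <- predicted$values
  keep <- which(acquired$mask$pattern)
  v <- assign_lines(v, acquired$line_dim, keep,
                    index_lines(acquired$values, acquired$line_dim, keep))
  kspace_frame(v, NULL, acquired$frame_index, acquired$line_dim)
}

#' Zero-fill interpolation to a finer grid
#'
#' Pads k-space symmetrically with zeros (in centered order) to `target_dims`
#' and inverse-transforms, rescaling so image values at the original voxel
#' centers are preserved up to interpolation ringing.
#'
#' @param k fully sampled [kspace_frame()]
#' @param target_dims target voxel counts, each >= the source dimension
#' @return [complex_image_frame()] on the target grid
#' @export
zero_fill_interpolate <- function(k, target_dims) {
  if (!inherits(k, "kspace_frame")) stop("k must be a kspace_frame")
  if (!is_fully_sampled(k)) stop("k-space frame has unacquired lines")
  src <- dim(k$values)
  if (length(target_dims) != length(src)) stop("target_dims rank mismatch")
  if (any(target_dims < src)) stop("target dims must be >= source dims")
  padded <- array(0i, dim = target_dims)
  lo <- (target_dims - src) %/% 2L
  idx <- lapply(seq_along(src), function(ax) lo[ax] + seq_len(src[ax]))
  padded <- do.call(`[<-`, c(list(padded), idx, list(k$values)))
  scale <- sqrt(prod(target_dims) / prod(src))
  complex_image_frame(uifft(ifftshift(padded)) * scale, k$frame_index)
}
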