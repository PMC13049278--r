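# Internal numerics helpers shared across modules.

#' Discrete Fourier transform sample frequencies
#'
#' Frequencies in cycles per unit length for an `n`-point DFT with sample
#' spacing `d`, in standard DFT order (DC first, negative frequencies in the
#' upper half).
#'
#' @param n number of samples
#' @param d sample spacing (any length unit; frequencies come back in cycles
#'   per that unit)
#' @return numeric vector of length `n`
#' @keywords internal
#' @noRd
fft_freq <- function(n, d = 1) {
  if (n < 1L) stop("n must be >= 1")
  if (d <= 0) stop("sample spacing must be positive")
  m <- 0:(n - 1L)
  m[m > n %/% 2] <- m[m > n %/% 2] - n
  m / (n * d)
}

#' Wrap phase into (-pi, pi]
#' @keywords internal
#' @noRd
wrap_phase <- function(x) atan2(sin(x), cos(x))

# Unitary n-dimensional FFT pair (Parseval-preserving).
ufft <- function(x) stats::fft(x) / sqrt(length(x))
uifft <- function(x) stats::fft(x, inverse = TRUE) / sqrt(length(x))

# Plain inverse FFT with 1/N normalization (for internal spectral stepping).
ifftn <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# Circularly shift array `x` along axis `ax` by `by` (positive = towards
# higher indices), keeping dimensions. Used by the finite-difference stencil.
axshift <- function(x, ax, by) {
  d <- dim(x)
  n <- d[ax]
  idx <- ((seq_len(n) - 1L - by) %% n) + 1L
  args <- rep(list(quote(expr = )), length(d))
  args[[ax]] <- idx
  do.call(`[`, c(list(x), args, list(drop = FALSE)))
}

# Swap halves along every axis (DC moved to the array center), and inverse.
fftshift <- function(x) {
  for (ax in seq_along(dim(x))) {
    n <- dim(x)[ax]
    x <- axshift(x, ax, n %/% 2)
  }
  x
}

ifftshift <- function(x) {
  for (ax in seq_along(dim(x))) {
    n <- dim(x)[ax]
    x <- axshift(x, ax, -(n %/% 2))
  }
  x
}

# Extract / assign full "lines" of an array along dimension `line_dim`.
index_lines <- function(x, line_dim, lines) {
  args <- rep(list(quote(expr = )), length(dim(x)))
  args[[line_dim]] <- lines
  do.call(`[`, c(list(x), args, list(drop = FALSE)))
}

assign_lines <- function(x, line_dim, lines, value) {
  args <- rep(list(quote(expr = )), length(dim(x)))
  args[[line_dim]] <- lines
  do.call(`[<-`, c(list(x), args, list(value)))
}

# Argument checks ------------------------------------------------------------

check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  if (nonneg && x < 0)
    stop(sprintf("'%s' must be >= 0", name), call. = FALSE)
  invisible(x)
}

as_spatial_array <- function(x) {
  if (is.null(dim(x))) array(x, dim = length(x)) else x
}

same_dims <- function(a, b) identical(dim(as_spatial_array(a)), dim(as_spatial_array(b)))

`%||%` <- function(a, b) if (is.null(a)) b else a
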