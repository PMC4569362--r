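# Separable Gaussian smoothing with zero padding.
#
# Implemented directly (rather than via FFT convolution) so boundary
# handling is explicit: the image is zero-padded, so smoothing alone
# loses mass near edges; density_from_points() renormalizes afterwards.

gaussian_kernel <- function(sigma) {
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- stats::dnorm(seq.int(-r, r), sd = sigma)
  k / sum(k)
}

# Correlation of v with kernel k (symmetric, odd length), zero-padded.
conv1 <- function(v, k) {
  r <- (length(k) - 1L) %/% 2L
  n <- length(v)
  vp <- c(numeric(r), v, numeric(r))
  out <- numeric(n)
  for (j in seq_along(k)) {
    out <- out + k[j] * vp[j:(j + n - 1L)]
  }
  out
}

#' Gaussian-blur a grid
#'
#' Isotropic Gaussian smoothing by separable 1-D passes with zero
#' padding; the kernel is truncated at 4 standard deviations.
#'
#' @param grid `(height x width)` numeric matrix.
#' @param sigma Standard deviation in pixels; `sigma <= 0` returns the
#'   grid unchanged.
#' @param edge_correct Divide by the blurred all-ones mask so border
#'   pixels are averages over the in-image kernel support instead of
#'   being attenuated toward zero. Without it, smoothing alone dims the
#'   image borders, which would inject an artificial central emphasis
#'   into any blurred prediction map.
#' @return The smoothed matrix.
#' @export
blur_gaussian <- function(grid, sigma, edge_correct = FALSE) {
  if (sigma <= 0) return(grid)
  k <- gaussian_kernel(sigma)
  pass2 <- function(g) {
    cols_done <- apply(g, 2L, conv1, k = k)            # down each column
    t(apply(cols_done, 1L, conv1, k = k))              # along each row
  }
  out <- pass2(grid)
  if (edge_correct) {
    out <- out / pass2(matrix(1, nrow(grid), ncol(grid)))
  }
  out
}

#' Map a discrete blur level to a Gaussian sigma in pixels
#'
#' Blur levels are dimensionless integers; level `L` corresponds to
#' `sigma = L * sigma_per_level * max(height, width)` pixels. The
#' default `sigma_per_level = 0.01` makes one level equal 1% of the
#' larger image dimension.
#'
#' @param blur_level Integer >= 0.
#' @param shape `c(height, width)`.
#' @param sigma_per_level Fraction of the larger dimension per level.
#' @return Sigma in pixels (0 when `blur_level` is 0).
#' @export
blur_sigma <- function(blur_level, shape, sigma_per_level = 0.01) {
  if (blur_level < 0) stopf("blur_level must be >= 0")
  blur_level * sigma_per_level * max(shape)
}
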