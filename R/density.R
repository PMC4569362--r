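#' Fixation-density map from selection points
#'
#' Converts discrete selection points into a continuous density map:
#' points are binned into a per-pixel impulse (count) map, convolved
#' with an isotropic Gaussian whose sigma follows [blur_sigma()], and
#' renormalized to unit mass. Blur level 0 yields the normalized
#' impulse map itself. This is the standard smoothing step of saliency
#' evaluation: a held-out observer is scored against the density of the
#' remaining observers' points, and a density map is itself a valid
#' predictor in ROC scoring.
#'
#' @param points Data.frame with 0-based pixel columns `x`, `y` (or a
#'   2-column matrix). Repeated points accumulate mass.
#' @param shape `c(height, width)` of the target grid.
#' @param blur_level Integer blur level >= 0.
#' @param sigma_per_level Fraction of `max(shape)` per blur level.
#' @return A `density_map`: list with `grid` (nonnegative, sums to 1)
#'   and `blur_level`.
#' @examples
#' d <- density_from_points(data.frame(x = 3, y = 4), c(16, 16),
#'                          blur_level = 2)
#' sum(d$grid)
#' @export
density_from_points <- function(points, shape, blur_level = 0L,
                                sigma_per_level = 0.01) {
  points <- as_points(points)
  if (nrow(points) == 0L) stopf("cannot build a density map from zero points")
  check_points_in_bounds(points, shape)
  if (blur_level < 0) stopf("blur_level must be >= 0")

  counts <- tabulate(points_to_index(points, shape),
                     nbins = shape[1L] * shape[2L])
  grid <- matrix(as.numeric(counts), nrow = shape[1L], ncol = shape[2L])
  sigma <- blur_sigma(blur_level, shape, sigma_per_level)
  if (sigma > 0) grid <- blur_gaussian(grid, sigma)
  grid <- grid / sum(grid)
  structure(list(grid = grid, blur_level = as.integer(blur_level)),
            class = "density_map")
}
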