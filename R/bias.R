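#' @name center-bias
#' @title Spatial (center) bias of saliency algorithms
#'
#' @description
#' Human observers concentrate selections near the image center, and
#' many saliency algorithms build a matching spatial preference into
#' their output — some explicitly, some through border effects. Because
#' standard ROC scoring rewards any map that mimics the spatial
#' distribution of positives, an algorithm's center bias inflates its
#' apparent performance regardless of how well it tracks image content.
#' This module quantifies an algorithm's spatial bias over a dataset
#' and removes it by either of two per-pixel normalizations across the
#' ensemble of the algorithm's maps.
NULL

#' Relative spatial bias of an algorithm's map ensemble
#'
#' Each map is first whitened to zero mean and unit (population)
#' standard deviation so maps contribute on a common scale. The
#' whitened maps are averaged across the ensemble, and the grand mean
#' of that average is subtracted. Image content uncorrelated across
#' images averages out, leaving the spatial preference the algorithm
#' applies everywhere: the result has zero mean, positive where the
#' algorithm systematically over-scores and negative where it
#' under-scores.
#'
#' @param ensemble A [map_ensemble()]; every map must be non-constant.
#' @return A `bias_profile`: list with the zero-mean `grid` and
#'   `algorithm_id`.
#' @export
spatial_bias_map <- function(ensemble) {
  whitened <- lapply(ensemble$maps, function(m) {
    s <- sd_pop(m$grid)
    if (s == 0) {
      stopf("map '%s' of algorithm '%s' is constant; cannot whiten",
            m$image_id, ensemble$algorithm_id)
    }
    (m$grid - mean(m$grid)) / s
  })
  avg <- Reduce(`+`, whitened) / length(whitened)
  structure(list(grid = avg - mean(avg),
                 algorithm_id = ensemble$algorithm_id),
            class = "bias_profile")
}

ensemble_as_matrix <- function(ensemble) {
  vapply(ensemble$maps, function(m) as.vector(m$grid),
         numeric(prod(ensemble$shape)))
}

matrix_as_ensemble <- function(mat, ensemble) {
  maps <- lapply(seq_along(ensemble$maps), function(i) {
    saliency_map(matrix(mat[, i], nrow = ensemble$shape[1L]),
                 image_id = ensemble$maps[[i]]$image_id,
                 algorithm_id = ensemble$algorithm_id)
  })
  map_ensemble(maps, algorithm_id = ensemble$algorithm_id)
}

#' Remove spatial bias by per-pixel rank ordering
#'
#' At every pixel location, the N values the algorithm produced across
#' the dataset's images are replaced by their ascending rank divided by
#' N, so each location carries the value set `{1/N, ..., 1}` (ties get
#' midranks). This forces an identical, uniform per-pixel score
#' distribution everywhere on the image: no location can be favored
#' across the dataset. For tie-free input the per-pixel sum across maps
#' is `(N + 1) / 2`.
#'
#' @param ensemble A [map_ensemble()] of N >= 2 maps.
#' @return A [map_ensemble()] of rank-normalized maps.
#' @export
debias_rank <- function(ensemble) {
  mat <- ensemble_as_matrix(ensemble)
  n <- ncol(mat)
  ranks <- t(apply(mat, 1L, rank)) / n
  matrix_as_ensemble(ranks, ensemble)
}

#' Remove spatial bias by pixel-wise whitening
#'
#' Two-stage whitening: each map is first whitened to zero mean and
#' unit population standard deviation (placing maps on a common scale),
#' then the N values at each pixel location are whitened across maps.
#' Afterwards every pixel location has zero mean and unit variance
#' across the dataset, so the per-pixel sum across maps is 0.
#'
#' @param ensemble A [map_ensemble()]; no map may be constant and no
#'   pixel location may be constant across the stage-1 maps.
#' @return A [map_ensemble()] of whitened maps.
#' @export
debias_whiten <- function(ensemble) {
  mat <- ensemble_as_matrix(ensemble)
  for (i in seq_len(ncol(mat))) {
    s <- sd_pop(mat[, i])
    if (s == 0) {
      stopf("map '%s' of algorithm '%s' is constant; cannot whiten",
            ensemble$maps[[i]]$image_id, ensemble$algorithm_id)
    }
    mat[, i] <- (mat[, i] - mean(mat[, i])) / s
  }
  matrix_as_ensemble(whiten_pixels(mat, ensemble$shape), ensemble)
}

# Stage 2: whiten each pixel location (row) across maps (columns);
# idempotent.
whiten_pixels <- function(mat, shape) {
  mu <- rowMeans(mat)
  s <- sqrt(rowMeans((mat - mu)^2))
  if (any(s == 0)) {
    bad <- index_to_points(which(s == 0)[1L], shape)
    stopf("pixel (x=%d, y=%d) is constant across maps; cannot whiten",
          bad$x, bad$y)
  }
  (mat - mu) / s
}

#' Center-bias ratio curve of a point set
#'
#' For concentric circles centered on the image center with radii
#' evenly spaced up to half the image diagonal, reports the fraction of
#' points falling inside each circle. A curve rising faster than the
#' uniform-area baseline indicates central concentration.
#'
#' @param points Data.frame with 0-based `x`, `y` (or 2-column matrix).
#' @param shape `c(height, width)` of the image.
#' @param n_radii Number of radii (default 20).
#' @return A `bias_ratio_curve`: list with `radii` (pixels, increasing)
#'   and `ratio` (non-decreasing fractions, ending at 1).
#' @export
center_bias_ratio <- function(points, shape, n_radii = 20L) {
  points <- as_points(points)
  if (nrow(points) == 0L) stopf("points must be non-empty")
  check_points_in_bounds(points, shape)
  h <- shape[1L]; w <- shape[2L]
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  r_max <- sqrt(h^2 + w^2) / 2
  radii <- seq(r_max / n_radii, r_max, length.out = n_radii)
  d <- sqrt((points$x - cx)^2 + (points$y - cy)^2)
  ratio <- vapply(radii, function(r) mean(d <= r), numeric(1L))
  structure(list(radii = radii, ratio = ratio),
            class = "bias_ratio_curve")
}
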