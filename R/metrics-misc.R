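#' Pearson correlation with validation
#'
#' Sample Pearson correlation between two equal-length vectors, used
#' for per-image score comparisons across tasks and for surrogate
#' benchmarking. Degenerate inputs (fewer than 3 pairs, or zero
#' variance in either vector) are errors rather than `NA`.
#'
#' @param xs,ys Numeric vectors of equal length >= 3.
#' @return The correlation coefficient in `[-1, 1]`.
#' @export
pearson_cor <- function(xs, ys) {
  if (length(xs) != length(ys)) stopf("xs and ys must have equal length")
  if (length(xs) < 3L) stopf("need at least 3 pairs")
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0) {
    stopf("zero variance: correlation undefined")
  }
  stats::cor(xs, ys)
}

#' Precision-recall curve of a map against an object mask
#'
#' The map is binarized at 256 evenly spaced thresholds over `[0, 1]`
#' (descending). At each threshold `t`, pixels with value `>= t` form
#' the predicted set; precision is the fraction of predicted pixels
#' inside the mask (1 when the predicted set is empty, avoiding 0/0 at
#' the top threshold), recall the fraction of mask pixels predicted.
#' The F-measure is the harmonic mean
#' `precision * recall / (0.5 * (precision + recall))`.
#'
#' @param map A [saliency_map()] or matrix with values in `[0, 1]`.
#' @param mask Logical or 0/1 matrix of the same shape with at least
#'   one positive pixel.
#' @param n_thresholds Number of thresholds (default 256).
#' @return A `pr_curve`: list with `thresholds` (descending),
#'   `precision`, `recall`, `f_measure`, and `max_f`.
#' @export
pr_curve <- function(map, mask, n_thresholds = 256L) {
  grid <- as_grid(map)
  mask <- as_grid(mask) > 0
  if (!all(dim(mask) == dim(grid))) stopf("mask shape does not match map")
  n_mask <- sum(mask)
  if (n_mask == 0L) stopf("mask has no positive pixel")
  if (min(grid) < 0 || max(grid) > 1) stopf("map values must lie in [0, 1]")

  thresholds <- seq(1, 0, length.out = n_thresholds)
  precision <- numeric(n_thresholds)
  recall <- numeric(n_thresholds)
  for (i in seq_along(thresholds)) {
    bin <- grid >= thresholds[i]
    n_bin <- sum(bin)
    tp <- sum(bin & mask)
    precision[i] <- if (n_bin == 0L) 1 else tp / n_bin
    recall[i] <- tp / n_mask
  }
  denom <- 0.5 * (precision + recall)
  f <- ifelse(denom > 0, precision * recall / denom, 0)
  structure(list(thresholds = thresholds, precision = precision,
                 recall = recall, f_measure = f, max_f = max(f)),
            class = "pr_curve")
}

#' Write per-image metric reports as CSV
#'
#' @param report Data.frame of metric rows (e.g. from
#'   [benchmark_algorithms()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metric_report <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
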