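#' @name roc-auc
#' @title Standard and shuffled ROC analysis of saliency maps
#'
#' @description
#' Both scores rate how well a map separates selected locations
#' (positives) from a negative sample, as the area under the ROC curve.
#' The AUC is computed as the normalized Mann-Whitney U statistic with
#' midranks for ties, which equals trapezoidal integration of the ROC
#' curve over all thresholds and handles tied map values exactly.
#'
#' The two scores differ only in where negatives come from:
#'
#' * **Standard AUC** draws negatives uniformly from the image's
#'   non-selected pixels. Any spatial bias shared by the map and the
#'   observers — above all the tendency of both to favor the image
#'   center — inflates this score.
#' * **Shuffled AUC** draws negatives from locations selected on
#'   *other* images of the dataset, so the negative sample carries the
#'   same spatial distribution as the positives. A map that encodes
#'   only the shared spatial bias then scores at chance (0.5).
NULL

# Normalized Mann-Whitney U with midranks; exact under ties.
mw_auc <- function(pos_vals, neg_vals) {
  np <- length(pos_vals)
  nn <- length(neg_vals)
  r <- rank(c(pos_vals, neg_vals))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

roc_result <- function(auc, n_pos, n_neg) {
  structure(list(auc = auc, n_pos = as.integer(n_pos),
                 n_neg = as.integer(n_neg)),
            class = "roc_result")
}

#' @rdname roc-auc
#' @param map A [saliency_map()], `density_map`, or numeric matrix.
#' @param positives Selected locations: data.frame with 0-based `x`,
#'   `y` columns (repeats keep their multiplicity) or 2-column matrix.
#' @param n_neg_ratio Negatives drawn per positive
#'   (`ceiling(n_neg_ratio * n_pos)`, capped at the number of available
#'   non-positive pixels).
#' @param seed Integer seed for the negative sample, or `NULL` to use
#'   the ambient RNG stream.
#' @return A `roc_result`: list with `auc` in `[0, 1]`, `n_pos`,
#'   `n_neg`.
#' @export
standard_auc <- function(map, positives, n_neg_ratio = 1, seed = NULL) {
  grid <- as_grid(map)
  shape <- dim(grid)
  positives <- as_points(positives)
  if (nrow(positives) == 0L) stopf("positives must be non-empty")
  check_points_in_bounds(positives, shape, "positive")

  pos_idx <- points_to_index(positives, shape)
  candidates <- setdiff(seq_len(shape[1L] * shape[2L]), unique(pos_idx))
  if (length(candidates) == 0L) {
    stopf("positives cover every pixel; no negatives available")
  }
  n_neg <- min(ceiling(n_neg_ratio * length(pos_idx)), length(candidates))
  neg_idx <- with_seed(seed, {
    candidates[sample.int(length(candidates), n_neg)]
  })
  roc_result(mw_auc(grid[pos_idx], grid[neg_idx]),
             n_pos = length(pos_idx), n_neg = n_neg)
}

#' @rdname roc-auc
#' @param negative_pool Candidate negatives: selection points pooled
#'   from the other images of the dataset (same format as `positives`;
#'   multiplicity kept).
#' @param max_neg_ratio Cap on negatives as a multiple of `n_pos`;
#'   larger pools are subsampled (seeded) to bound cost.
#' @export
shuffled_auc <- function(map, positives, negative_pool,
                         max_neg_ratio = 10, seed = NULL) {
  grid <- as_grid(map)
  shape <- dim(grid)
  positives <- as_points(positives)
  if (nrow(positives) == 0L) stopf("positives must be non-empty")
  check_points_in_bounds(positives, shape, "positive")
  pool <- as_points(negative_pool)
  check_points_in_bounds(pool, shape, "negative-pool point")

  pos_idx <- points_to_index(positives, shape)
  pool_idx <- points_to_index(pool, shape)
  pool_idx <- pool_idx[!pool_idx %in% unique(pos_idx)]
  if (length(pool_idx) == 0L) {
    stopf("negative pool is empty after excluding positive locations")
  }
  cap <- ceiling(max_neg_ratio * length(pos_idx))
  neg_idx <- if (length(pool_idx) > cap) {
    with_seed(seed, pool_idx[sample.int(length(pool_idx), cap)])
  } else {
    pool_idx
  }
  roc_result(mw_auc(grid[pos_idx], grid[neg_idx]),
             n_pos = length(pos_idx), n_neg = length(neg_idx))
}
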