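#' Simulate explicit-judgment points from a predicted judgment map
#'
#' Converts a continuous judgment map into discrete surrogate judgment
#' points: the map is min-max normalized, locations whose normalized
#' value falls below `threshold` are excluded, and `n_points` locations
#' are drawn with replacement with probability proportional to the
#' normalized value. Sampling with replacement is intentional: human
#' judgment points can coincide, and multiplicity carries information.
#'
#' @param map A [saliency_map()] or matrix.
#' @param n_points Number of simulated points (default 100, matching
#'   the typical number of human judgment points per image).
#' @param threshold Exclusion threshold on the normalized map in
#'   `[0, 1)` (default 0.1).
#' @param seed Integer seed or `NULL`.
#' @return Data.frame with 0-based `x`, `y`, one row per draw
#'   (duplicates retained).
#' @export
simulate_judgments <- function(map, n_points = 100L, threshold = 0.1,
                               seed = NULL) {
  if (n_points < 1L) stopf("n_points must be >= 1")
  if (threshold < 0 || threshold >= 1) stopf("threshold must lie in [0, 1)")
  grid <- as_grid(map)
  if (max(grid) == min(grid)) stopf("thresholded map empty: map is constant")
  norm <- rescale01(grid)
  prob <- ifelse(norm >= threshold, norm, 0)
  if (sum(prob) == 0) stopf("thresholded map empty: no pixel at or above %.3f",
                            threshold)
  idx <- with_seed(seed, {
    sample.int(length(prob), size = n_points, replace = TRUE, prob = prob)
  })
  index_to_points(idx, dim(grid))
}

#' Package simulated points as a point table
#'
#' @param points Data.frame of `x`, `y` draws from
#'   [simulate_judgments()].
#' @param image_id Image the points belong to.
#' @param observer_id Synthetic observer label (default `"sim1"`).
#' @return A [point_table()] with task `explicit_judgment` and
#'   sequential ordinals.
#' @export
simulated_point_table <- function(points, image_id, observer_id = "sim1") {
  point_table(data.frame(
    image_id = image_id, observer_id = observer_id,
    task = "explicit_judgment", x = points$x, y = points$y,
    ordinal = seq_len(nrow(points)) - 1L, stringsAsFactors = FALSE
  ))
}

# Mean AUC of one algorithm's maps against a point source.
mean_auc_for_source <- function(ensemble, source, metric, n_neg_ratio) {
  images <- intersect(names(ensemble$maps), unique(source$image_id))
  if (length(images) == 0L) {
    stopf("algorithm '%s' shares no image with the point source",
          ensemble$algorithm_id)
  }
  aucs <- vapply(images, function(img) {
    pos <- filter_points(source, img)[, c("x", "y")]
    m <- ensemble_map(ensemble, img)
    if (metric == "standard") {
      standard_auc(m, pos, n_neg_ratio = n_neg_ratio)$auc
    } else {
      pool <- source[source$image_id != img, c("x", "y")]
      shuffled_auc(m, pos, pool)$auc
    }
  }, numeric(1L))
  mean(aucs)
}

#' Surrogate benchmarking: do simulated judgments rank algorithms like
#' real ones?
#'
#' Scores each algorithm's maps against two point sources — typically
#' true explicit judgments and simulated ones — and reports the
#' correlation between the two per-algorithm score vectors. A high
#' correlation means the surrogate data ranks algorithms like the real
#' data, so simulated judgments can stand in when only gaze data is
#' available.
#'
#' @param algorithms Named list of [map_ensemble()] (>= 3 algorithms).
#' @param true_points,sim_points [point_table()]s covering the same
#'   images; each algorithm is scored against both.
#' @param metric `"standard"` or `"shuffled"` ROC analysis.
#' @param cor_method `"pearson"` (default) or `"spearman"`.
#' @param n_neg_ratio Negatives per positive for the standard metric.
#' @param seed Seed for ROC negative samples.
#' @return List with `auc_true`, `auc_sim` (named per-algorithm mean
#'   AUCs) and `correlation`.
#' @export
surrogate_benchmark <- function(algorithms, true_points, sim_points,
                                metric = c("standard", "shuffled"),
                                cor_method = c("pearson", "spearman"),
                                n_neg_ratio = 1, seed = NULL) {
  metric <- match.arg(metric)
  cor_method <- match.arg(cor_method)
  if (length(algorithms) < 3L) {
    stopf("surrogate benchmarking needs >= 3 algorithms")
  }
  with_seed(seed, {
    # one shared negative-sample substream per source, so identical
    # point sources receive identical scores
    sub_seed <- sample.int(.Machine$integer.max, 1L)
    auc_true <- with_seed(sub_seed, {
      vapply(algorithms, mean_auc_for_source, numeric(1L),
             source = true_points, metric = metric,
             n_neg_ratio = n_neg_ratio)
    })
    auc_sim <- with_seed(sub_seed, {
      vapply(algorithms, mean_auc_for_source, numeric(1L),
            source = sim_points, metric = metric,
            n_neg_ratio = n_neg_ratio)
    })
    correlation <- if (cor_method == "pearson") {
      pearson_cor(auc_true, auc_sim)
    } else {
      stats::cor(auc_true, auc_sim, method = "spearman")
    }
    list(auc_true = auc_true, auc_sim = auc_sim,
         correlation = correlation)
  })
}
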