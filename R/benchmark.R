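#' Benchmark saliency algorithms against selection data
#'
#' Scores every algorithm's maps against the selection points of each
#' requested task with standard and/or shuffled ROC analysis,
#' optionally after center-bias removal of each algorithm's ensemble.
#' For the shuffled metric, an image's negative pool is the union of
#' same-task points from all other images of the dataset.
#'
#' @param maps Named list of [map_ensemble()] keyed by algorithm id.
#' @param points A [point_table()] covering the benchmarked images.
#' @param tasks Tasks to score (default: the tasks present in
#'   `points`).
#' @param metrics Subset of `c("standard", "shuffled")`.
#' @param debias `"none"`, `"rank"` ([debias_rank()]) or `"whiten"`
#'   ([debias_whiten()]) applied per algorithm before scoring.
#' @param n_neg_ratio Negatives per positive for the standard metric.
#' @param max_neg_ratio Pool cap multiple for the shuffled metric.
#' @param seed Seed driving all negative samples.
#' @return Data.frame with columns `algorithm_id`, `image_id`, `task`,
#'   `metric`, `auc`, one row per scored combination.
#' @export
benchmark_algorithms <- function(maps, points,
                                 tasks = unique(points$task),
                                 metrics = c("standard", "shuffled"),
                                 debias = c("none", "rank", "whiten"),
                                 n_neg_ratio = 1, max_neg_ratio = 10,
                                 seed = NULL) {
  debias <- match.arg(debias)
  metrics <- match.arg(metrics, several.ok = TRUE)
  with_seed(seed, {
    rows <- list()
    for (alg in names(maps)) {
      ens <- maps[[alg]]
      ens <- switch(debias, none = ens, rank = debias_rank(ens),
                    whiten = debias_whiten(ens))
      for (task in tasks) {
        task_pts <- points[points$task == task, , drop = FALSE]
        images <- intersect(names(ens$maps), unique(task_pts$image_id))
        for (img in images) {
          pos <- filter_points(task_pts, img)[, c("x", "y")]
          m <- ensemble_map(ens, img)
          for (metric in metrics) {
            auc <- if (metric == "standard") {
              standard_auc(m, pos, n_neg_ratio = n_neg_ratio)$auc
            } else {
              pool <- task_pts[task_pts$image_id != img, c("x", "y")]
              shuffled_auc(m, pos, pool, max_neg_ratio = max_neg_ratio)$auc
            }
            rows[[length(rows) + 1L]] <- data.frame(
              algorithm_id = alg, image_id = img, task = task,
              metric = metric, auc = auc, stringsAsFactors = FALSE)
          }
        }
      }
    }
    do.call(rbind, rows)
  })
}

#' @rdname benchmark_algorithms
#' @param report A [benchmark_algorithms()] result.
#' @return `summarize_benchmark()`: mean AUC per
#'   (algorithm, task, metric).
#' @export
summarize_benchmark <- function(report) {
  agg <- stats::aggregate(auc ~ algorithm_id + task + metric,
                          data = report, FUN = mean)
  agg[order(agg$algorithm_id, agg$task, agg$metric), , drop = FALSE]
}
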