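#' Inter-observer congruency (IOC)
#'
#' IOC measures how well one observer's selections are predicted by the
#' pooled selections of the remaining observers, and serves as an
#' empirical ceiling on algorithm performance: no content-driven model
#' is expected to predict an observer better than the other observers
#' do.
#'
#' For each observer of an (image, task) pair, the other observers'
#' points are converted to a Gaussian-blurred density map
#' ([density_from_points()]) and the held-out observer's points are
#' scored against it with [standard_auc()]; the per-image IOC is the
#' mean over held-out observers. `ioc_dataset()` averages the per-image
#' scores over all images with at least two observers.
#'
#' @param table A [point_table()].
#' @param image_id Image to score.
#' @param task One of [POINT_TASKS].
#' @param catalog [image_catalog()] giving image dimensions.
#' @param blur_level,sigma_per_level Blur of the leave-one-out density
#'   map (see [blur_sigma()]).
#' @param n_neg_ratio Negatives per positive in the inner ROC analysis.
#' @param seed Seed for the negative samples; held-out observers are
#'   scored from one seeded stream.
#' @return `ioc_image()`: the mean leave-one-observer-out AUC.
#' @export
ioc_image <- function(table, image_id, task, catalog, blur_level = 3L,
                      sigma_per_level = 0.01, n_neg_ratio = 1,
                      seed = NULL) {
  pts <- filter_points(table, image_id, task)
  observers <- unique(pts$observer_id)
  if (length(observers) < 2L) {
    stopf("IOC for image '%s', task '%s' needs >= 2 observers (found %d)",
          image_id, task, length(observers))
  }
  shape <- catalog_shape(catalog, image_id)
  with_seed(seed, {
    aucs <- vapply(observers, function(obs) {
      held_out <- pts[pts$observer_id == obs, c("x", "y")]
      others <- pts[pts$observer_id != obs, c("x", "y")]
      dens <- density_from_points(others, shape, blur_level = blur_level,
                                  sigma_per_level = sigma_per_level)
      standard_auc(dens, held_out, n_neg_ratio = n_neg_ratio)$auc
    }, numeric(1L))
    mean(aucs)
  })
}

#' @rdname ioc_image
#' @return `ioc_dataset()`: list with `ioc` (mean over images),
#'   `per_image` (data.frame of image_id and ioc).
#' @export
ioc_dataset <- function(table, task, catalog, blur_level = 3L,
                        sigma_per_level = 0.01, n_neg_ratio = 1,
                        seed = NULL) {
  task_pts <- table[table$task == task, , drop = FALSE]
  eligible <- vapply(unique(task_pts$image_id), function(img) {
    length(unique(task_pts$observer_id[task_pts$image_id == img])) >= 2L
  }, logical(1L))
  images <- unique(task_pts$image_id)[eligible]
  if (length(images) == 0L) {
    stopf("no image has >= 2 observers for task '%s'", task)
  }
  with_seed(seed, {
    per_image <- vapply(images, function(img) {
      ioc_image(table, img, task, catalog, blur_level = blur_level,
                sigma_per_level = sigma_per_level,
                n_neg_ratio = n_neg_ratio)
    }, numeric(1L))
    list(ioc = mean(per_image),
         per_image = data.frame(image_id = images, ioc = unname(per_image),
                                stringsAsFactors = FALSE))
  })
}
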