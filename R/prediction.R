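#' @name judgment-prediction
#' @title Predicting explicit-judgment locations from saliency and
#'   fixation features
#'
#' @description
#' Explicit judgments — locations observers manually select as most
#' salient — are expensive to collect. This module trains an ensemble
#' of bagged regression trees (a random forest used as a regressor) to
#' predict judgment locations from per-pixel features: the outputs of
#' several saliency algorithms, optionally the Gaussian-blurred density
#' of free-viewing fixations, and optionally normalized pixel
#' coordinates. Judgment points are positive samples (label 1); seeded
#' uniform draws from the remaining pixels are negatives (label 0).
#' Applying the trained model at every pixel of an unseen image yields
#' a predicted judgment map, which is smoothed and rescaled before
#' evaluation. Center-bias removal is deliberately not applied inside
#' this module, since spatial position is usually itself a feature.
NULL

#' Feature schema for judgment prediction
#'
#' @param algorithm_ids Ordered character vector of saliency algorithms
#'   whose map values become features.
#' @param use_fixation_density Include the blurred free-viewing
#'   fixation density as a feature.
#' @param use_xy Include `x/width` and `y/height` as features.
#' @param blur_level,sigma_per_level Blur of the fixation-density
#'   feature (see [blur_sigma()]).
#' @return A `feature_schema`.
#' @export
feature_schema <- function(algorithm_ids = character(),
                           use_fixation_density = TRUE, use_xy = TRUE,
                           blur_level = 4L, sigma_per_level = 0.01) {
  if (length(algorithm_ids) == 0L && !use_fixation_density && !use_xy) {
    stopf("feature schema must enable at least one feature source")
  }
  structure(list(algorithm_ids = as.character(algorithm_ids),
                 use_fixation_density = isTRUE(use_fixation_density),
                 use_xy = isTRUE(use_xy),
                 blur_level = as.integer(blur_level),
                 sigma_per_level = sigma_per_level),
            class = "feature_schema")
}

schema_feature_names <- function(schema) {
  c(schema$algorithm_ids,
    if (schema$use_fixation_density) "fixation_density",
    if (schema$use_xy) c("x_norm", "y_norm"))
}

# Feature matrix for given 0-based pixel indices of one image.
image_features <- function(image_id, idx, maps, fixations, schema, shape) {
  pts <- index_to_points(idx, shape)
  cols <- list()
  for (alg in schema$algorithm_ids) {
    ens <- maps[[alg]]
    if (is.null(ens)) stopf("no map ensemble for algorithm '%s'", alg)
    cols[[alg]] <- as.vector(ensemble_map(ens, image_id)$grid)[idx]
  }
  if (schema$use_fixation_density) {
    fix <- filter_points(fixations, image_id)
    if (nrow(fix) == 0L) {
      stopf("no fixations available for image '%s' (needed for the density feature)",
            image_id)
    }
    dens <- density_from_points(fix[, c("x", "y")], shape,
                                blur_level = schema$blur_level,
                                sigma_per_level = schema$sigma_per_level)
    cols[["fixation_density"]] <- as.vector(dens$grid)[idx]
  }
  if (schema$use_xy) {
    cols[["x_norm"]] <- pts$x / shape[2L]
    cols[["y_norm"]] <- pts$y / shape[1L]
  }
  do.call(cbind, cols)
}

#' Split images into training and test halves
#'
#' Seeded disjoint half/half split of the image set; for an odd count
#' the training half gets the extra image.
#'
#' @param image_ids Character vector of >= 2 image ids.
#' @param seed Integer seed.
#' @return List with `train` and `test` id vectors.
#' @export
split_images <- function(image_ids, seed) {
  image_ids <- unique(as.character(image_ids))
  if (length(image_ids) < 2L) stopf("need >= 2 images to split")
  shuffled <- with_seed(seed, sample(image_ids))
  n_train <- ceiling(length(shuffled) / 2)
  list(train = sort(shuffled[seq_len(n_train)]),
       test = sort(shuffled[-seq_len(n_train)]))
}

#' Assemble the judgment-prediction training set
#'
#' Per image, every explicit-judgment point becomes a positive sample
#' and `n_neg_per_image` seeded uniform draws from pixels not among the
#' positives become negatives; features follow the schema.
#'
#' @param judgments [point_table()] of explicit-judgment points
#'   (positives); rows with other tasks are ignored.
#' @param maps Named list of [map_ensemble()] keyed by algorithm id.
#' @param fixations [point_table()] of free-viewing fixations (used
#'   only when the schema includes the density feature).
#' @param schema A [feature_schema()].
#' @param catalog An [image_catalog()].
#' @param n_neg_per_image Negative samples per image (default 100,
#'   matching the judgment count per image so classes are balanced).
#' @param seed Integer seed for negative sampling.
#' @return A `training_set`: list with `features` (matrix), `labels`
#'   (0/1), `provenance` (data.frame image_id, x, y), and `schema`.
#' @export
build_training_set <- function(judgments, maps, fixations, schema,
                               catalog, n_neg_per_image = 100L, seed) {
  jd <- judgments[judgments$task == "explicit_judgment", , drop = FALSE]
  if (nrow(jd) == 0L) stopf("no explicit-judgment rows in 'judgments'")
  images <- unique(jd$image_id)
  with_seed(seed, {
    parts <- lapply(images, function(img) {
      shape <- catalog_shape(catalog, img)
      pos <- jd[jd$image_id == img, c("x", "y")]
      pos_idx <- points_to_index(pos, shape)
      candidates <- setdiff(seq_len(prod(shape)), unique(pos_idx))
      if (length(candidates) < n_neg_per_image) {
        stopf("image '%s' has too few non-positive pixels for %d negatives",
              img, n_neg_per_image)
      }
      neg_idx <- candidates[sample.int(length(candidates), n_neg_per_image)]
      idx <- c(pos_idx, neg_idx)
      feats <- image_features(img, idx, maps, fixations, schema, shape)
      prov <- cbind(image_id = img, index_to_points(idx, shape))
      list(features = feats,
           labels = c(rep(1, length(pos_idx)), rep(0, length(neg_idx))),
           provenance = prov)
    })
    structure(list(
      features = do.call(rbind, lapply(parts, `[[`, "features")),
      labels = unlist(lapply(parts, `[[`, "labels")),
      provenance = do.call(rbind, lapply(parts, `[[`, "provenance")),
      schema = schema
    ), class = "training_set")
  })
}

#' Train the bagged-regression-tree judgment predictor
#'
#' Fits a random forest regressor (bootstrap resample per tree, random
#' feature subset of size `ceiling(sqrt(d))` per split, prediction =
#' mean over trees) to the 0/1 labels of a [build_training_set()]
#' output. The default of 15 trees is the package's standard operating
#' point; sensitivity to the tree count is part of the evaluation
#' protocol.
#'
#' @param ts A `training_set`.
#' @param n_trees Number of trees (default 15).
#' @param seed Integer seed; training is deterministic given it.
#' @return A `judgment_predictor`: list with the fitted `model`,
#'   `n_trees`, `schema`, `seed`, and `train_images`.
#' @export
train_judgment_predictor <- function(ts, n_trees = 15L, seed) {
  if (length(unique(ts$labels)) < 2L) {
    stopf("training set must contain both positive and negative labels")
  }
  d <- ncol(ts$features)
  model <- with_seed(seed, {
    # 0/1 labels fit with a regressor is the intended design; silence
    # randomForest's few-unique-values advisory.
    suppressWarnings(randomForest::randomForest(
      x = ts$features, y = ts$labels,
      ntree = as.integer(n_trees), mtry = ceiling(sqrt(d))
    ))
  })
  structure(list(model = model, n_trees = as.integer(n_trees),
                 schema = ts$schema, seed = seed,
                 train_images = sort(unique(ts$provenance$image_id))),
            class = "judgment_predictor")
}

#' Predict a full-image explicit-judgment map
#'
#' Applies the trained model at every pixel, clamps predictions to
#' `[0, 1]`, Gaussian-blurs the result at `blur_level` (0 disables
#' smoothing), and min-max rescales to `[0, 1]`. Post-processing blur
#' is conventional in saliency evaluation and the default level 4 is
#' the package's standard operating point.
#'
#' @param predictor A [train_judgment_predictor()] result.
#' @param image_id Image to predict.
#' @param maps,fixations,catalog As in [build_training_set()].
#' @param blur_level Post-processing blur level (default 4).
#' @param sigma_per_level Sigma fraction per level for the post blur.
#' @return A [saliency_map()] with `algorithm_id = "judgment_predictor"`.
#' @export
predict_judgment_map <- function(predictor, image_id, maps, fixations,
                                 catalog, blur_level = 4L,
                                 sigma_per_level = 0.01) {
  schema <- predictor$schema
  shape <- catalog_shape(catalog, image_id)
  idx <- seq_len(prod(shape))
  feats <- image_features(image_id, idx, maps, fixations, schema, shape)
  pred <- stats::predict(predictor$model, feats)
  pred <- pmin(pmax(as.numeric(pred), 0), 1)
  grid <- matrix(pred, nrow = shape[1L])
  sigma <- blur_sigma(blur_level, shape, sigma_per_level)
  if (sigma > 0) grid <- blur_gaussian(grid, sigma, edge_correct = TRUE)
  saliency_map(rescale01(grid), image_id = image_id,
               algorithm_id = "judgment_predictor")
}

#' Evaluate a judgment predictor on held-out images
#'
#' Predicts a judgment map for every test image and scores it against
#' that image's explicit-judgment points with standard or shuffled ROC
#' analysis (for shuffled, the negative pool is the judgment points of
#' the other test images). Any overlap between test images and the
#' predictor's training images is an error: leakage is structurally
#' excluded rather than merely discouraged.
#'
#' @param predictor A `judgment_predictor`.
#' @param test_ids Character vector of held-out image ids.
#' @param judgments,maps,fixations,catalog As in
#'   [build_training_set()].
#' @param metric `"standard"` or `"shuffled"`.
#' @param blur_level Post-processing blur for the predicted maps.
#' @param n_neg_ratio Negatives per positive for the standard metric.
#' @param seed Seed for the ROC negative samples.
#' @return List with `per_image` (data.frame image_id, auc) and
#'   `mean_auc`.
#' @export
evaluate_predictor <- function(predictor, test_ids, judgments, maps,
                               fixations, catalog,
                               metric = c("standard", "shuffled"),
                               blur_level = 4L, n_neg_ratio = 1,
                               seed = NULL) {
  metric <- match.arg(metric)
  overlap <- intersect(test_ids, predictor$train_images)
  if (length(overlap) > 0L) {
    stopf("test images overlap training images: %s",
          paste(overlap, collapse = ", "))
  }
  jd <- judgments[judgments$task == "explicit_judgment", , drop = FALSE]
  with_seed(seed, {
    aucs <- vapply(test_ids, function(img) {
      m <- predict_judgment_map(predictor, img, maps, fixations, catalog,
                                blur_level = blur_level,
                                sigma_per_level = predictor$schema$sigma_per_level)
      pos <- jd[jd$image_id == img, c("x", "y")]
      if (nrow(pos) == 0L) stopf("no judgment points for test image '%s'", img)
      if (metric == "standard") {
        standard_auc(m, pos, n_neg_ratio = n_neg_ratio)$auc
      } else {
        pool <- jd[jd$image_id != img, c("x", "y")]
        shuffled_auc(m, pos, pool)$auc
      }
    }, numeric(1L))
    list(per_image = data.frame(image_id = test_ids, auc = unname(aucs),
                                stringsAsFactors = FALSE),
         mean_auc = mean(aucs))
  })
}
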