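#' @name synthetic-data
#' @title Synthetic multi-observer gaze and judgment datasets
#'
#' @description
#' Seed-deterministic generators that emulate the structure of a
#' multi-task fixation-plus-judgment study. Each synthetic scene has a
#' latent salience density (a Gaussian-blob mixture standing in for
#' image content). Observers select points from a mixture of that
#' latent density and a central Gaussian, with a task-specific mixture
#' weight encoding the empirical ordering of center bias across tasks:
#' strongest under free viewing, weakest for explicit judgment.
#' Synthetic "algorithms" produce maps equal to the latent density
#' corrupted by i.i.d. noise (fidelity) plus an injected central bump
#' (built-in center bias), so evaluation, bias quantification, bias
#' removal, and predictor training are all exercisable without any
#' external dataset.
NULL

#' Default center-bias mixture weight per task
#'
#' Fraction of points drawn from the central Gaussian rather than the
#' latent salience, by task. Free viewing is most center-biased and
#' explicit judgment least; the values are package defaults encoding
#' that qualitative ordering.
#' @export
TASK_CENTER_WEIGHTS <- c(free_view = 0.5, saliency_view = 0.3,
                         object_search = 0.2, explicit_judgment = 0.05)

#' Generate a synthetic scene
#'
#' Places `n_blobs` Gaussian blobs uniformly inside a margin of 15% of
#' the smaller image dimension, with per-blob sigma drawn from 5-12% of
#' that dimension and weight from 0.5-1.5. The latent salience density
#' is the normalized blob mixture.
#'
#' @param shape `c(height, width)`.
#' @param n_blobs Number of salient blobs (>= 1).
#' @param seed Integer seed or `NULL` to draw from the ambient stream.
#' @param image_id Identifier for the scene.
#' @return A `scene_model`: list with `image_id`, `shape`, `blobs`,
#'   and `latent` (matrix summing to 1).
#' @export
gen_scene <- function(shape = c(64L, 64L), n_blobs = 2L, seed = NULL,
                      image_id = "scene") {
  if (n_blobs < 1L) stopf("n_blobs must be >= 1")
  h <- shape[1L]; w <- shape[2L]
  margin <- round(0.15 * min(h, w))
  if (w - 1L - 2L * margin < 1L || h - 1L - 2L * margin < 1L) {
    stopf("shape %dx%d too small to place blobs inside the margin", w, h)
  }
  with_seed(seed, {
    blobs <- lapply(seq_len(n_blobs), function(i) {
      list(cx = stats::runif(1L, margin, w - 1L - margin),
           cy = stats::runif(1L, margin, h - 1L - margin),
           sigma = stats::runif(1L, 0.05, 0.12) * min(h, w),
           weight = stats::runif(1L, 0.5, 1.5))
    })
    xs <- matrix(rep(0:(w - 1L), each = h), nrow = h)
    ys <- matrix(rep(0:(h - 1L), times = w), nrow = h)
    latent <- matrix(0, h, w)
    for (b in blobs) {
      latent <- latent + b$weight *
        exp(-((xs - b$cx)^2 + (ys - b$cy)^2) / (2 * b$sigma^2))
    }
    structure(list(image_id = as.character(image_id), shape = shape,
                   blobs = blobs, latent = latent / sum(latent)),
              class = "scene_model")
  })
}

#' Observer model
#'
#' @param center_bias_weight Mixture weight of the central Gaussian in
#'   `[0, 1]`, or `NULL` to use the task default
#'   ([TASK_CENTER_WEIGHTS]).
#' @param center_sigma Central-Gaussian sigma as a fraction of the
#'   smaller image dimension (default 0.15).
#' @param point_jitter Per-point Gaussian jitter in pixels applied
#'   after location choice (default 1).
#' @param n_points_per_task Points each observer contributes per image
#'   and task (default 10).
#' @return An `observer_model`.
#' @export
observer_model <- function(center_bias_weight = NULL, center_sigma = 0.15,
                           point_jitter = 1, n_points_per_task = 10L) {
  if (!is.null(center_bias_weight) &&
      (center_bias_weight < 0 || center_bias_weight > 1)) {
    stopf("center_bias_weight must lie in [0, 1]")
  }
  structure(list(center_bias_weight = center_bias_weight,
                 center_sigma = center_sigma,
                 point_jitter = point_jitter,
                 n_points_per_task = as.integer(n_points_per_task)),
            class = "observer_model")
}

clip_int <- function(v, lo, hi) pmin(pmax(as.integer(round(v)), lo), hi)

#' Generate selection points for one scene
#'
#' Each point is drawn from the mixture
#' `(1 - w) * latent + w * central Gaussian` with `w` the observer's
#' center-bias weight (task default if unset), then jittered by
#' rounded Gaussian noise and clipped to bounds. Ordinals number each
#' observer's points sequentially from 0.
#'
#' @param scene A [gen_scene()] result.
#' @param observer An [observer_model()].
#' @param task One of [POINT_TASKS].
#' @param n_observers Number of observers to simulate.
#' @param seed Integer seed or `NULL`.
#' @return A [point_table()].
#' @export
gen_points <- function(scene, observer = observer_model(), task,
                       n_observers, seed = NULL) {
  if (!task %in% POINT_TASKS) stopf("unknown task '%s'", task)
  w_center <- observer$center_bias_weight
  if (is.null(w_center)) w_center <- TASK_CENTER_WEIGHTS[[task]]
  h <- scene$shape[1L]; w <- scene$shape[2L]
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  sigma_c <- observer$center_sigma * min(h, w)
  n <- observer$n_points_per_task
  latent_vec <- as.vector(scene$latent)

  with_seed(seed, {
    rows <- lapply(seq_len(n_observers), function(o) {
      from_center <- stats::runif(n) < w_center
      x <- integer(n); y <- integer(n)
      n_c <- sum(from_center)
      if (n_c > 0L) {
        x[from_center] <- clip_int(stats::rnorm(n_c, cx, sigma_c), 0L, w - 1L)
        y[from_center] <- clip_int(stats::rnorm(n_c, cy, sigma_c), 0L, h - 1L)
      }
      n_l <- n - n_c
      if (n_l > 0L) {
        idx <- sample.int(h * w, n_l, replace = TRUE, prob = latent_vec)
        pts <- index_to_points(idx, scene$shape)
        x[!from_center] <- pts$x
        y[!from_center] <- pts$y
      }
      if (observer$point_jitter > 0) {
        x <- clip_int(x + stats::rnorm(n, 0, observer$point_jitter), 0L, w - 1L)
        y <- clip_int(y + stats::rnorm(n, 0, observer$point_jitter), 0L, h - 1L)
      }
      data.frame(image_id = scene$image_id,
                 observer_id = sprintf("obs%02d", o),
                 task = task, x = x, y = y, ordinal = seq_len(n) - 1L,
                 stringsAsFactors = FALSE)
    })
    point_table(do.call(rbind, rows))
  })
}

#' Synthetic saliency-algorithm model
#'
#' A synthetic algorithm reproduces the latent salience (rescaled to
#' peak 1) corrupted by i.i.d. Gaussian noise of `fidelity_noise_sd`,
#' plus an injected central Gaussian bump of height `bias_amplitude`
#' and width `bias_sigma_frac * min(shape)` — the algorithm's built-in
#' center bias. The final map is min-max rescaled to `[0, 1]`.
#'
#' @param algorithm_id Identifier.
#' @param fidelity_noise_sd Noise standard deviation (>= 0) on the
#'   peak-1 latent scale; lower means higher fidelity.
#' @param bias_amplitude Height of the injected central bump on the
#'   same scale (0 = unbiased).
#' @param bias_sigma_frac Bump sigma as a fraction of the smaller image
#'   dimension.
#' @return An `algorithm_model`.
#' @export
algorithm_model <- function(algorithm_id, fidelity_noise_sd,
                            bias_amplitude = 0, bias_sigma_frac = 0.25) {
  if (!is.finite(fidelity_noise_sd) || fidelity_noise_sd < 0) {
    stopf("fidelity_noise_sd must be finite and >= 0")
  }
  structure(list(algorithm_id = as.character(algorithm_id),
                 fidelity_noise_sd = fidelity_noise_sd,
                 bias_amplitude = bias_amplitude,
                 bias_sigma_frac = bias_sigma_frac),
            class = "algorithm_model")
}

center_bump <- function(shape, sigma_frac, amplitude) {
  h <- shape[1L]; w <- shape[2L]
  xs <- matrix(rep(0:(w - 1L), each = h), nrow = h)
  ys <- matrix(rep(0:(h - 1L), times = w), nrow = h)
  sigma <- sigma_frac * min(h, w)
  amplitude * exp(-((xs - (w - 1) / 2)^2 + (ys - (h - 1) / 2)^2) /
                    (2 * sigma^2))
}

#' Generate a synthetic algorithm's maps for a set of scenes
#'
#' @param scenes List of [gen_scene()] results (>= 2, same shape).
#' @param model An [algorithm_model()].
#' @param seed Integer seed or `NULL`.
#' @return A [map_ensemble()].
#' @export
gen_algorithm_maps <- function(scenes, model, seed = NULL) {
  shape <- scenes[[1L]]$shape
  bias <- center_bump(shape, model$bias_sigma_frac, model$bias_amplitude)
  with_seed(seed, {
    maps <- lapply(scenes, function(sc) {
      base <- sc$latent / max(sc$latent)
      noise <- matrix(stats::rnorm(prod(shape), 0, model$fidelity_noise_sd),
                      nrow = shape[1L])
      saliency_map(rescale01(base + noise + bias),
                   image_id = sc$image_id,
                   algorithm_id = model$algorithm_id)
    })
    map_ensemble(maps, algorithm_id = model$algorithm_id)
  })
}

#' Binary object mask from a scene's latent salience
#'
#' Thresholds the latent density at `level` times its maximum,
#' emulating a segmented salient-object mask.
#'
#' @param scene A [gen_scene()] result.
#' @param level Threshold fraction in (0, 1).
#' @return A logical `(height x width)` matrix.
#' @export
gen_masks <- function(scene, level = 0.5) {
  if (level <= 0 || level >= 1) stopf("level must lie in (0, 1)")
  mask <- scene$latent >= level * max(scene$latent)
  if (!any(mask)) stopf("mask is empty at level %.3f", level)
  mask
}

#' Default synthetic algorithm roster
#'
#' Six synthetic algorithms crossing fidelity (noise level) with
#' built-in center bias, so that bias-sensitive and bias-robust
#' evaluation disagree about their ranking. The roster includes a
#' high-fidelity unbiased algorithm and a low-fidelity strongly biased
#' one whose raw-vs-debiased ordering exercises the fairness analyses.
#' @export
default_algorithm_roster <- function() {
  list(
    algorithm_model("hifi_clean", fidelity_noise_sd = 0.08),
    algorithm_model("midfi_mildbias", fidelity_noise_sd = 0.15,
                    bias_amplitude = 0.5),
    algorithm_model("midfi_clean", fidelity_noise_sd = 0.25),
    algorithm_model("lofi_strongbias", fidelity_noise_sd = 0.5,
                    bias_amplitude = 2),
    algorithm_model("lofi_clean", fidelity_noise_sd = 0.6),
    algorithm_model("midfi_strongbias", fidelity_noise_sd = 0.2,
                    bias_amplitude = 1.2)
  )
}

#' Configuration of a full synthetic benchmark scenario
#'
#' @param n_images Number of scenes (default 20).
#' @param shape Grid shape `c(height, width)` (default 64x64; small
#'   enough that exhaustive oracles stay feasible).
#' @param n_blobs Blobs per scene.
#' @param n_observers Observers per task.
#' @param n_points_per_task Points per observer, image and task.
#' @param center_sigma,point_jitter Observer-model parameters.
#' @param algorithms List of [algorithm_model()]s.
#' @param mask_level Mask threshold fraction.
#' @param tasks Tasks to generate points for.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(n_images = 20L, shape = c(64L, 64L),
                            n_blobs = 2L, n_observers = 10L,
                            n_points_per_task = 10L, center_sigma = 0.15,
                            point_jitter = 1,
                            algorithms = default_algorithm_roster(),
                            mask_level = 0.5, tasks = POINT_TASKS) {
  structure(list(n_images = as.integer(n_images), shape = as.integer(shape),
                 n_blobs = as.integer(n_blobs),
                 n_observers = as.integer(n_observers),
                 n_points_per_task = as.integer(n_points_per_task),
                 center_sigma = center_sigma, point_jitter = point_jitter,
                 algorithms = algorithms, mask_level = mask_level,
                 tasks = tasks),
            class = "scenario_config")
}

#' Generate a complete synthetic benchmark scenario
#'
#' Composes scenes, per-task point tables, per-algorithm map
#' ensembles, and object masks into one in-memory dataset. All
#' randomness flows from `seed`; identical `(config, seed)` pairs
#' reproduce the scenario exactly.
#'
#' @param config A [scenario_config()].
#' @param seed Integer seed.
#' @return A `benchmark_scenario`: list with `config`, `seed`,
#'   `catalog`, `scenes`, `points` (one [point_table()] covering all
#'   tasks), `maps` (named list of [map_ensemble()]), `masks` (named
#'   list of logical matrices).
#' @export
gen_benchmark_scenario <- function(config = scenario_config(), seed) {
  with_seed(seed, {
    ids <- sprintf("img%03d", seq_len(config$n_images))
    scenes <- lapply(ids, function(id) {
      gen_scene(config$shape, config$n_blobs, seed = NULL, image_id = id)
    })
    names(scenes) <- ids
    catalog <- image_catalog(ids, width = config$shape[2L],
                             height = config$shape[1L])
    obs <- observer_model(center_sigma = config$center_sigma,
                          point_jitter = config$point_jitter,
                          n_points_per_task = config$n_points_per_task)
    points <- do.call(rbind, lapply(config$tasks, function(task) {
      do.call(rbind, lapply(scenes, function(sc) {
        gen_points(sc, obs, task, config$n_observers, seed = NULL)
      }))
    }))
    rownames(points) <- NULL
    points <- point_table(points, catalog)
    maps <- lapply(config$algorithms, function(am) {
      gen_algorithm_maps(scenes, am, seed = NULL)
    })
    names(maps) <- vapply(config$algorithms, `[[`, character(1L),
                          "algorithm_id")
    masks <- lapply(scenes, gen_masks, level = config$mask_level)
    structure(list(config = config, seed = seed, catalog = catalog,
                   scenes = scenes, points = points, maps = maps,
                   masks = masks),
              class = "benchmark_scenario")
  })
}
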