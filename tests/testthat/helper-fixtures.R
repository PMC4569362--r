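# Shared fixtures and independent oracles.

# Exhaustive pairwise-comparison AUC: P(pos > neg) + 0.5 P(pos == neg).
oracle_auc <- function(pos_vals, neg_vals) {
  cmp <- outer(pos_vals, neg_vals,
               function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Point table with every observer contributing the same rows.
identical_observer_table <- function(n_observers, x, y, image_id = "img1",
                                     task = "free_view") {
  point_table(do.call(rbind, lapply(seq_len(n_observers), function(o) {
    data.frame(image_id = image_id, observer_id = sprintf("o%02d", o),
               task = task, x = x, y = y,
               ordinal = seq_along(x) - 1L, stringsAsFactors = FALSE)
  })))
}

toy_catalog <- function(image_id = "img1", width = 64L, height = 64L) {
  image_catalog(image_id, width = width, height = height)
}

# The default synthetic study, generated once per test run.
default_scenario <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- gen_benchmark_scenario(seed = 42)
    cache
  }
})

# Train/test split and trained predictor on the default scenario,
# cached so the predictor-dependent tests share one fit.
default_predictor_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sc <- default_scenario()
      split <- split_images(sc$catalog$image_id, seed = 101)
      schema <- feature_schema(names(sc$maps))
      jd <- sc$points[sc$points$task == "explicit_judgment" &
                        sc$points$image_id %in% split$train, ]
      fix <- sc$points[sc$points$task == "free_view", ]
      ts <- build_training_set(jd, sc$maps, fix, schema, sc$catalog,
                               seed = 102)
      predictor <- train_judgment_predictor(ts, n_trees = 15, seed = 103)
      cache <<- list(scenario = sc, split = split, schema = schema,
                     training_set = ts, fixations = fix,
                     predictor = predictor)
    }
    cache
  }
})

# Central-Gaussian samples, rounded to the pixel grid.
draw_central_points <- function(n, shape, sigma_frac = 0.15) {
  h <- shape[1]; w <- shape[2]
  s <- sigma_frac * min(h, w)
  data.frame(
    x = pmin(pmax(round(rnorm(n, (w - 1) / 2, s)), 0), w - 1),
    y = pmin(pmax(round(rnorm(n, (h - 1) / 2, s)), 0), h - 1))
}
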