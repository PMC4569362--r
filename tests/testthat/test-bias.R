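make_noise_ensemble <- function(n, shape = c(16L, 16L), alg = "noise") {
  map_ensemble(lapply(seq_len(n), function(i) {
    saliency_map(matrix(runif(prod(shape)), shape[1L]),
                 image_id = sprintf("img%03d", i), algorithm_id = alg)
  }), algorithm_id = alg)
}

test_that("spatial bias maps are zero-mean and expose injected bias", {
  set.seed(51)
  # i.i.d. noise ensembles: the apparent bias shrinks as 1/sqrt(N)
  # (maximum over 1024 pixels of a mean of N whitened noise maps)
  small <- spatial_bias_map(make_noise_ensemble(20L, c(32L, 32L)))
  big <- spatial_bias_map(make_noise_ensemble(200L, c(32L, 32L)))
  expect_lt(abs(mean(big$grid)), 1e-9)
  expect_lt(max(abs(big$grid)), 4.5 / sqrt(200))
  expect_lt(max(abs(big$grid)), max(abs(small$grid)))

  # every map shares a central bump: the bias peaks at the center
  bump <- saliencybench:::center_bump(c(33L, 33L), 0.2, 1)
  biased <- map_ensemble(lapply(1:20, function(i) {
    saliency_map(matrix(runif(33 * 33), 33L) + bump,
                 image_id = sprintf("img%03d", i))
  }), algorithm_id = "b")
  bb <- spatial_bias_map(biased)
  expect_lt(abs(mean(bb$grid)), 1e-9)
  am <- which(bb$grid == max(bb$grid), arr.ind = TRUE)
  expect_lt(max(abs(unname(am[1L, ]) - c(17L, 17L))), 3)

  flat <- map_ensemble(list(
    saliency_map(matrix(1, 4L, 4L), "bad"),
    saliency_map(matrix(runif(16), 4L), "ok")), "a")
  expect_error(spatial_bias_map(flat), "map 'bad'.*constant")
})

test_that("rank de-biasing assigns ranks over N, with midranks for ties", {
  # pixel values (5, 2, 9) across 3 maps -> (2/3, 1/3, 1)
  ens3 <- map_ensemble(lapply(c(5, 2, 9), function(v) {
    saliency_map(matrix(v, 2L, 2L), paste0("i", v))
  }), "a")
  deb3 <- debias_rank(ens3)
  vals <- vapply(deb3$maps, function(m) m$grid[1L, 1L], numeric(1L))
  expect_equal(unname(vals), c(2 / 3, 1 / 3, 1))

  # tied values (7, 7, 1, 9) -> midranks (2.5, 2.5, 1, 4) / 4
  ens4 <- map_ensemble(lapply(seq_along(c(7, 7, 1, 9)), function(i) {
    saliency_map(matrix(c(7, 7, 1, 9)[i], 2L, 2L), paste0("i", i))
  }), "a")
  vals4 <- vapply(debias_rank(ens4)$maps, function(m) m$grid[1L, 1L],
                  numeric(1L))
  expect_equal(unname(vals4), c(0.625, 0.625, 0.25, 1))
})

test_that("rank de-biasing keeps the per-pixel sum identity and monotone invariance", {
  set.seed(52)
  for (n in c(2L, 5L, 50L)) {
    ens <- make_noise_ensemble(n)
    deb <- debias_rank(ens)
    sums <- Reduce(`+`, lapply(deb$maps, `[[`, "grid"))
    expect_equal(max(abs(sums - (n + 1) / 2)), 0)
  }
  # a single strictly increasing transform applied to all maps leaves
  # the rank-normalized output unchanged
  ens <- make_noise_ensemble(6L)
  warped <- map_ensemble(lapply(ens$maps, function(m) {
    saliency_map(exp(2 * m$grid), m$image_id)
  }), "w")
  d1 <- lapply(debias_rank(ens)$maps, `[[`, "grid")
  d2 <- lapply(debias_rank(warped)$maps, `[[`, "grid")
  expect_equal(unname(d1), unname(d2), tolerance = 1e-12)
})

test_that("whitening yields zero-sum unit-variance pixels and is idempotent", {
  set.seed(53)
  for (n in c(2L, 5L, 50L)) {
    ens <- make_noise_ensemble(n)
    deb <- debias_whiten(ens)
    mat <- sapply(deb$maps, function(m) as.vector(m$grid))
    expect_lt(max(abs(rowSums(mat))), 1e-9)
    expect_lt(max(abs(rowMeans(mat^2) - 1)), 1e-9)
  }
  # two-map case: every pixel pair becomes (-1, +1) in value order
  ens2 <- make_noise_ensemble(2L)
  deb2 <- debias_whiten(ens2)
  expect_true(all(sort(unique(round(deb2$maps[[1L]]$grid^2, 9))) == 1))

  # the pixel-wise whitening stage is idempotent
  ens <- make_noise_ensemble(8L)
  mat <- sapply(ens$maps, function(m) as.vector(m$grid))
  once_px <- saliencybench:::whiten_pixels(mat, c(16L, 16L))
  expect_equal(saliencybench:::whiten_pixels(once_px, c(16L, 16L)),
               once_px, tolerance = 1e-9)

  # a pixel constant across the stage-1 maps is an error naming the
  # location; two identical maps are constant at every pixel
  g1 <- matrix(runif(16), 4L)
  same <- map_ensemble(list(saliency_map(g1, "a"), saliency_map(g1, "b")),
                       "x")
  expect_error(debias_whiten(same), "constant across maps")
})

test_that("de-biased ensembles have (near-)flat spatial bias", {
  set.seed(54)
  bump <- saliencybench:::center_bump(c(16L, 16L), 0.25, 2)
  ens <- map_ensemble(lapply(1:40, function(i) {
    saliency_map(matrix(runif(256), 16L) + bump, sprintf("img%03d", i))
  }), "a")
  raw_bias <- max(abs(spatial_bias_map(ens)$grid))
  rank_bias <- max(abs(spatial_bias_map(debias_rank(ens))$grid))
  whiten_bias <- max(abs(spatial_bias_map(debias_whiten(ens))$grid))
  expect_gt(raw_bias, 1)           # the bump dominates before removal
  expect_lt(rank_bias, 3 / sqrt(40))
  expect_lt(whiten_bias, 3 / sqrt(40))
})

test_that("center-bias ratio curves behave geometrically", {
  # all points at the center: ratio 1 everywhere
  ctr <- center_bias_ratio(data.frame(x = rep(16L, 5L), y = rep(16L, 5L)),
                           c(33L, 33L))
  expect_true(all(ctr$ratio == 1))
  expect_true(all(diff(ctr$radii) > 0))

  # single corner point: 0 until the corner distance, then 1
  corner <- center_bias_ratio(data.frame(x = 0L, y = 0L), c(33L, 33L))
  d_corner <- sqrt(2) * 16
  expect_true(all(corner$ratio[corner$radii < d_corner] == 0))
  expect_true(all(corner$ratio[corner$radii >= d_corner] == 1))

  # uniform points: ratio tracks the circle/image area overlap
  set.seed(55)
  pts <- data.frame(x = sample(0:63, 2000L, TRUE),
                    y = sample(0:63, 2000L, TRUE))
  cur <- center_bias_ratio(pts, c(64L, 64L))
  xs <- rep(0:63, each = 64) - 31.5
  ys <- rep(0:63, times = 64) - 31.5
  d <- sqrt(xs^2 + ys^2)
  area_frac <- vapply(cur$radii, function(r) mean(d <= r), numeric(1L))
  expect_lt(max(abs(cur$ratio - area_frac)), 0.05)
  expect_equal(cur$ratio[length(cur$ratio)], 1)
  expect_true(all(diff(cur$ratio) >= 0))
})
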