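test_that("density maps conserve mass and place it where the points are", {
  # blur level 0: a single point is a unit impulse
  d0 <- density_from_points(data.frame(x = 3L, y = 5L), c(8L, 8L),
                            blur_level = 0L)
  expect_equal(d0$grid[6L, 4L], 1)
  expect_equal(sum(d0$grid), 1)

  # centered point at any blur: argmax stays put, mass stays 1
  for (lev in c(1L, 3L, 7L)) {
    d <- density_from_points(data.frame(x = 16L, y = 16L), c(33L, 33L),
                             blur_level = lev)
    expect_equal(sum(d$grid), 1, tolerance = 1e-9)
    am <- which(d$grid == max(d$grid), arr.ind = TRUE)
    expect_equal(unname(am[1L, ]), c(17L, 17L))
  }

  # two far-apart points with a small sigma: two equal masses of 0.5
  d2 <- density_from_points(data.frame(x = c(8L, 24L), y = c(8L, 24L)),
                            c(32L, 32L), blur_level = 1L,
                            sigma_per_level = 1 / 32)  # sigma = 1 px
  left <- sum(d2$grid[1:16, 1:16])
  right <- sum(d2$grid[17:32, 17:32])
  expect_equal(left, 0.5, tolerance = 1e-6)
  expect_equal(right, 0.5, tolerance = 1e-6)

  expect_error(density_from_points(data.frame(x = integer(),
                                              y = integer()),
                                   c(8L, 8L)), "zero points")
})

test_that("separable Gaussian blur matches a direct 2-D convolution", {
  set.seed(21)
  g <- matrix(runif(12 * 9), 9L, 12L)
  sigma <- 1.3
  k <- saliencybench:::gaussian_kernel(sigma)
  r <- (length(k) - 1L) %/% 2L
  k2 <- outer(k, k)
  direct <- matrix(0, 9L, 12L)
  pad <- matrix(0, 9L + 2L * r, 12L + 2L * r)
  pad[(r + 1):(r + 9), (r + 1):(r + 12)] <- g
  for (i in 1:9) for (j in 1:12) {
    direct[i, j] <- sum(pad[i:(i + 2L * r), j:(j + 2L * r)] * k2)
  }
  expect_equal(blur_gaussian(g, sigma), direct, tolerance = 1e-12)
})

test_that("standard AUC equals the exhaustive pair oracle and handles ties", {
  # constant map: all ties, midranks give exactly 0.5
  const <- saliency_map(matrix(0.3, 8L, 8L), "c")
  expect_equal(standard_auc(const, data.frame(x = 1:3, y = 1:3),
                            seed = 1)$auc, 0.5)

  # perfect map: 1 on positives, 0 elsewhere
  g <- matrix(0, 8L, 8L); g[cbind(2:4, 2:4)] <- 1
  perfect <- saliency_map(g, "p")
  expect_equal(standard_auc(perfect, data.frame(x = 1:3, y = 1:3),
                            seed = 1)$auc, 1)

  # 4x4 rasterized 1..16, positives = 3 largest cells, all 13 rest
  # as negatives
  g16 <- matrix(1:16, 4L, 4L)
  pos <- data.frame(x = 3L, y = 1:3)  # cells 14, 15, 16
  res <- standard_auc(saliency_map(g16 / 16, "g"), pos,
                      n_neg_ratio = 13 / 3, seed = 2)
  expect_equal(res$n_neg, 13L)
  expect_equal(res$auc, oracle_auc(c(14, 15, 16), setdiff(1:16, 14:16)))
})

test_that("both AUC operations equal the oracle on random tied instances", {
  set.seed(99)
  for (i in 1:25) {
    h <- sample(5:9, 1L); w <- sample(5:9, 1L)
    g <- matrix(sample(0:6, h * w, replace = TRUE) / 6, h, w)
    m <- saliency_map(g, "m")
    n_pos <- sample(2:6, 1L)
    all_pts <- expand.grid(x = 0:(w - 1L), y = 0:(h - 1L))
    pos <- all_pts[sample.int(nrow(all_pts), n_pos), ]

    res <- standard_auc(m, pos, n_neg_ratio = h * w, seed = i)
    pos_idx <- pos$x * h + pos$y + 1L
    expect_equal(res$auc,
                 oracle_auc(g[pos_idx], g[-pos_idx]), tolerance = 1e-12)

    pool <- all_pts[sample.int(nrow(all_pts), 30L, replace = TRUE), ]
    keep <- !(pool$x * h + pool$y + 1L) %in% pos_idx
    if (sum(keep) == 0L) next
    res_s <- shuffled_auc(m, pos, pool, max_neg_ratio = 1e6)
    pool_idx <- (pool$x * h + pool$y + 1L)[keep]
    expect_equal(res_s$auc, oracle_auc(g[pos_idx], g[pool_idx]),
                 tolerance = 1e-12)
  }
})

test_that("standard AUC is invariant under strictly monotone transforms", {
  set.seed(31)
  g <- matrix(runif(100), 10L, 10L)
  pos <- data.frame(x = sample(0:9, 5L), y = sample(0:9, 5L))
  a1 <- standard_auc(saliency_map(g, "a"), pos, seed = 5)$auc
  a2 <- standard_auc(saliency_map(exp(3 * g) / exp(3), "b"), pos,
                     seed = 5)$auc
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("shuffled AUC neutralizes a purely central map", {
  shape <- c(512L, 512L)
  cmap <- saliencybench:::center_bump(shape, 0.15, 1)
  set.seed(11)
  pos <- draw_central_points(2000L, shape)
  pool <- draw_central_points(2000L, shape)
  s <- shuffled_auc(cmap, pos, pool, max_neg_ratio = 1e6, seed = 1)$auc
  expect_lt(abs(s - 0.5), 0.03)
  expect_gt(standard_auc(cmap, pos, seed = 2)$auc, 0.6)
  expect_error(shuffled_auc(cmap, pos, pos[1L, ]), "pool is empty")
})

test_that("IOC is high for congruent observers and at chance for incongruent ones", {
  cat64 <- toy_catalog()
  shared <- identical_observer_table(5L, x = rep(30L, 3L), y = rep(30L, 3L))
  expect_gte(ioc_image(shared, "img1", "free_view", cat64, seed = 1), 0.99)

  set.seed(5)
  unif <- point_table(do.call(rbind, lapply(1:20, function(o) {
    data.frame(image_id = "img1", observer_id = sprintf("o%02d", o),
               task = "free_view", x = sample(0:63, 10L, TRUE),
               y = sample(0:63, 10L, TRUE), ordinal = 0:9)
  })))
  expect_lt(abs(ioc_image(unif, "img1", "free_view", cat64, seed = 2) - 0.5),
            0.05)

  # two observers at far-apart points, blur much smaller than the
  # separation: each held-out point misses the other's blob
  cat32 <- toy_catalog(width = 32L, height = 32L)
  far <- point_table(data.frame(
    image_id = "img1", observer_id = c("a", "b"), task = "free_view",
    x = c(4L, 28L), y = c(4L, 28L), ordinal = 0L))
  ioc_far <- ioc_image(far, "img1", "free_view", cat32, blur_level = 1L,
                       sigma_per_level = 1 / 32, seed = 3)
  expect_lt(abs(ioc_far - 0.5), 0.05)

  solo <- far[far$observer_id == "a", ]
  expect_error(ioc_image(point_table(solo), "img1", "free_view", cat32),
               ">= 2 observers")
})

test_that("dataset IOC averages per-image scores", {
  cat3 <- image_catalog(c("i1", "i2", "i3"), 32L, 32L)
  set.seed(6)
  tab <- point_table(do.call(rbind, lapply(c("i1", "i2", "i3"), function(img) {
    do.call(rbind, lapply(1:4, function(o) {
      data.frame(image_id = img, observer_id = sprintf("o%d", o),
                 task = "free_view", x = sample(0:31, 5L, TRUE),
                 y = sample(0:31, 5L, TRUE), ordinal = 0:4)
    }))
  })))
  res <- ioc_dataset(tab, "free_view", cat3, seed = 9)
  expect_equal(res$ioc, mean(res$per_image$ioc))
  expect_equal(sort(res$per_image$image_id), c("i1", "i2", "i3"))
  # single-image dataset equals the per-image score
  one <- tab[tab$image_id == "i1", ]
  res1 <- ioc_dataset(point_table(one), "free_view", cat3, seed = 9)
  expect_equal(res1$ioc, res1$per_image$ioc[1L])
  expect_error(ioc_dataset(tab, "object_search", cat3), "no image")
})

test_that("pearson_cor matches hand values and rejects degenerate input", {
  expect_equal(pearson_cor(1:5, 1:5), 1)
  expect_equal(pearson_cor(1:5, -(1:5)), -1)
  expect_equal(pearson_cor(c(1, 2, 3), c(1, 3, 2)), 0.5)
  expect_error(pearson_cor(1:3, rep(2, 3)), "zero variance")
  expect_error(pearson_cor(1:2, 1:2), "at least 3")
})

test_that("precision-recall curves match a brute-force oracle", {
  mask <- matrix(runif(64) > 0.6, 8L, 8L)
  while (!any(mask)) mask <- matrix(runif(64) > 0.6, 8L, 8L)
  exact <- saliency_map(mask * 1, "m")
  expect_equal(pr_curve(exact, mask)$max_f, 1)

  # direct formula check: P = 0.6, R = 0.3 gives F = 0.4
  expect_equal(0.6 * 0.3 / (0.5 * (0.6 + 0.3)), 0.4)

  set.seed(41)
  g <- matrix(runif(256), 16L, 16L)
  mk <- matrix(runif(256) > 0.5, 16L, 16L)
  pc <- pr_curve(saliency_map(g, "g"), mk)
  for (i in c(1L, 57L, 128L, 200L, 256L)) {
    t <- pc$thresholds[i]
    bin <- g >= t
    tp <- sum(bin & mk)
    p_exp <- if (sum(bin) == 0L) 1 else tp / sum(bin)
    expect_equal(pc$precision[i], p_exp)
    expect_equal(pc$recall[i], tp / sum(mk))
  }
  # recall is non-decreasing as the threshold falls; curve ends at 1
  expect_true(all(diff(pc$recall) >= 0))
  expect_equal(pc$recall[256L], 1)

  # the quoted F formula is the harmonic mean 2PR/(P+R)
  pr <- expand.grid(p = seq(0.05, 1, by = 0.05), r = seq(0.05, 1, by = 0.05))
  f1 <- pr$p * pr$r / (0.5 * (pr$p + pr$r))
  f2 <- 2 * pr$p * pr$r / (pr$p + pr$r)
  expect_equal(f1, f2, tolerance = 1e-12)

  expect_error(pr_curve(exact, mask & FALSE), "no positive pixel")
})
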