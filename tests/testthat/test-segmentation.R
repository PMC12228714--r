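test_that("brightness threshold retains pixels by mean(R,G,B) >= cut", {
  img <- random_image(31, 10, 10)
  expect_true(all(apply_brightness_threshold(img, 0)))

  one <- rgb_image(array(c(30, 0, 0), c(1, 1, 3)))
  expect_true(apply_brightness_threshold(one, 10)[1, 1])   # mean exactly 10

  mask <- apply_brightness_threshold(img, 128)
  a <- unclass(img)
  oracle <- matrix(FALSE, 10, 10)
  for (i in 1:10) for (j in 1:10) {
    oracle[i, j] <- mean(a[i, j, ]) >= 128
  }
  expect_identical(mask, oracle)
  dark <- uniform_image(1, 1, 1)
  expect_error(apply_brightness_threshold(dark, 50), "above threshold",
               class = "wf_empty_roi")
})

test_that("feature tables carry channels plus 0-based positions", {
  img <- rgb_image(array(c(10, 20, 1, 2, 5, 6), c(1, 2, 3)))
  tab <- build_feature_table(img, matrix(TRUE, 1, 2), scaling = "none")
  expect_equal(nrow(tab), 2)
  expect_named(tab, c("R", "G", "B", "x", "y"))
  expect_equal(tab$x, c(0, 1))
  expect_equal(tab$y, c(0, 0))
  expect_equal(tab$R, c(10, 20))

  const <- uniform_image(50, 60, 70, 3, 3)
  tabc <- build_feature_table(const, matrix(TRUE, 3, 3))
  expect_true(all(tabc$R == 0 & tabc$G == 0 & tabc$B == 0))

  rnd <- random_image(7, 8, 8)
  tabr <- build_feature_table(rnd, matrix(TRUE, 8, 8))
  expect_true(all(vapply(tabr, min, numeric(1)) == 0))
  expect_true(all(vapply(tabr, max, numeric(1)) == 1))
  expect_error(build_feature_table(rnd, matrix(TRUE, 8, 8), channels = character(0)))
})

test_that("k-means handles degenerate geometries", {
  two <- data.frame(x = c(0, 100), y = c(0, 100))
  fit <- kmeans_cluster(two, 2, seed = 1)
  expect_equal(fit$inertia, 0)
  expect_equal(length(unique(fit$cluster)), 2)

  same <- data.frame(x = rep(3, 10), y = rep(4, 10))
  fit1 <- kmeans_cluster(same, 1, seed = 1)
  expect_equal(fit1$inertia, 0)
  expect_error(kmeans_cluster(two, 5, seed = 1), "cannot form")
})

test_that("k-means finds the exhaustive minimum-inertia partition of blobs", {
  X <- withr::with_seed(13, {
    centres <- matrix(c(0, 0, 10, 0, 5, 9), 3, byrow = TRUE)
    do.call(rbind, lapply(1:3, function(b) {
      sweep(matrix(rnorm(6, 0, 0.3), 3, 2), 2, centres[b, ], `+`)
    }))
  })
  fit <- kmeans_cluster(as.data.frame(X), 3, seed = 2)
  expect_equal(fit$inertia, exhaustive_min_inertia(X, 3), tolerance = 1e-9)
  blob <- rep(1:3, each = 3)
  expect_equal(length(unique(paste(fit$cluster, blob))), 3)   # same partition
})

test_that("the k-means objective never increases across iterations", {
  feats <- build_feature_table(random_image(17, 12, 12), matrix(TRUE, 12, 12))
  for (s in 0:2) {
    fit <- kmeans_cluster(feats, 4, seed = s, n_init = 1)
    expect_true(all(diff(fit$inertia_trace) <= 1e-9))
  }
})

test_that("k-means is deterministic given a seed and matches an independent fit", {
  feats <- build_feature_table(random_image(19, 16, 16), matrix(TRUE, 16, 16))
  a <- kmeans_cluster(feats, 4, seed = 5)
  b <- kmeans_cluster(feats, 4, seed = 5)
  expect_identical(a$cluster, b$cluster)
  expect_identical(a$inertia, b$inertia)
  # an independent Lloyd implementation should not find a much better optimum
  ref <- stats::kmeans(as.matrix(feats), 4, nstart = 25, iter.max = 300,
                       algorithm = "Lloyd")
  expect_lte(a$inertia, ref$tot.withinss * 1.02)
})

test_that("canonical relabelling sorts clusters by mean intensity", {
  img <- rgb_image(array(c(rep(200, 2), rep(50, 2), rep(120, 2),
                           rep(0, 12)), c(1, 6, 3)))
  mask <- matrix(TRUE, 1, 6)
  raw <- c(1L, 1L, 2L, 2L, 3L, 3L)
  cmap <- relabel_and_stats(raw, img, mask, k = 4, order_channel = "R")
  expect_equal(cmap$stats$mean_R, c(50, 120, 200))
  expect_equal(cmap$stats$cluster, 1:3)
  expect_equal(sum(cmap$stats$n_pixels), sum(mask))
  expect_equal(sum(cmap$stats$area_fraction), 1, tolerance = 1e-9)

  # label permutation of the raw clustering leaves the canonical map unchanged
  perm <- c(2L, 3L, 1L)[raw]
  cmap2 <- relabel_and_stats(perm, img, mask, k = 4, order_channel = "R")
  expect_identical(cmap$labels, cmap2$labels)
})

test_that("a uniform wound collapses to one effective cluster", {
  img <- uniform_image(80, 80, 80, 6, 6)
  mask <- apply_brightness_threshold(img, 10)
  feats <- build_feature_table(img, mask, channels = c("R", "G", "B"))
  fit <- kmeans_cluster(feats[c("R", "G", "B")], 1, seed = 0)
  cmap <- relabel_and_stats(fit$cluster, img, mask, k = 5)
  st <- cmap$stats[cmap$stats$cluster > 0, ]
  expect_equal(nrow(st), 1)
  expect_equal(st$area_fraction, 1)
})

test_that("segmentation recovers the concentric phantom rings", {
  out <- ring_phantom(seed = 3)
  img <- select_focused(out$stack)
  cmap <- segment_wound(img, calibration = default_calibration())
  inside <- out$truth$wound_mask
  ari <- mclust::adjustedRandIndex(cmap$labels[inside], out$truth$rings[inside])
  expect_gte(ari, 0.9)
  st <- cmap$stats[cmap$stats$cluster > 0, ]
  expect_equal(st$cluster, 1:4)
  expect_true(all(diff(st$mean_ph) > 0))          # pH rises toward the centre
  # cluster 4 occupies the wound centre: its pixels sit nearest the middle
  lab <- cmap$labels
  centre <- (dim(lab) - 1) / 2
  mean_radius <- vapply(1:4, function(cl) {
    ij <- which(lab == cl, arr.ind = TRUE) - 1
    mean(sqrt((ij[, 1] - centre[1])^2 + (ij[, 2] - centre[2])^2))
  }, numeric(1))
  expect_equal(which.min(mean_radius), 4L)
  expect_true(all(diff(mean_radius) < 0))          # concentric ordering
  # elements per cluster account for every retained pixel
  expect_equal(sum(st$n_pixels), sum(lab > 0))
})

test_that("the background-clustering mode maps sub-threshold pixels to 0", {
  out <- ring_phantom(seed = 5, size = 64)
  img <- select_focused(out$stack)
  cmap <- segment_wound(img, background = "cluster")
  # the cluster mapped to 0 is dominated by sub-threshold pixels
  bg_pixels <- cmap$labels == 0
  expect_gt(mean(!out$truth$wound_mask[bg_pixels]), 0.5)
  expect_lte(max(cmap$labels), 4)
})

test_that("the inertia curve is elbow-shaped on blob data and hits zero", {
  X <- withr::with_seed(23, {
    centres <- matrix(c(0, 0, 20, 0, 10, 17), 3, byrow = TRUE)
    do.call(rbind, lapply(1:3, function(b) {
      sweep(matrix(rnorm(20, 0, 0.5), 10, 2), 2, centres[b, ], `+`)
    }))
  })
  curve <- inertia_curve(as.data.frame(X), 1:5, seed = 1)
  expect_true(all(diff(curve$inertia) <= 1e-9))
  drop23 <- curve$inertia[2] - curve$inertia[3]
  drop34 <- curve$inertia[3] - curve$inertia[4]
  expect_gt(drop23, 10 * drop34)

  tiny <- data.frame(x = 1:4, y = 1:4)
  expect_equal(inertia_curve(tiny, 4, seed = 1)$inertia, 0)
  dup <- data.frame(x = rep(1, 5), y = rep(2, 5))
  expect_equal(inertia_curve(dup, 1, seed = 1)$inertia, 0)
  expect_error(inertia_curve(tiny, 1:10, seed = 1), "exceeds")
})
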