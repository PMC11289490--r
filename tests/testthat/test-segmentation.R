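test_that("photometric jitter is seeded, bounded and rank-preserving", {
  x <- rand_img(16, 16, seed = 1) * 0.6 + 0.2   # stay clear of clipping
  expect_identical(photometric_transform(x, 3), photometric_transform(x, 3))
  ident <- photometric_transform(x, 5, jitter = list(brightness = 0,
                                                     contrast = 0, gamma = 0))
  expect_equal(ident, x, tolerance = 1e-12)
  y <- photometric_transform(x, 7, jitter = list(brightness = 0, contrast = 0,
                                                 gamma = 0.3))
  expect_equal(cor(rank(as.vector(x)), rank(as.vector(y))), 1)
  expect_true(all(y >= 0 & y <= 1))
  expect_error(photometric_transform(x, 1, jitter = list(brightness = 0.1,
                                                         contrast = 1.2,
                                                         gamma = 0)),
               "jitter")
})

test_that("geometric transforms invert exactly on the pixel grid", {
  x <- rand_img(8, 8, seed = 2)
  flip <- list(type = "hflip")
  expect_identical(geometric_transform(geometric_transform(x, flip), flip), x)
  labels <- matrix(sample.int(4L, 64L, replace = TRUE), 8, 8)
  moved <- geometric_transform(labels, flip)
  expect_identical(tabulate(moved, 4L), tabulate(labels, 4L))
  resc <- list(type = "rescale", factor = 2L)
  z <- rand_feat(6, 6, 3, seed = 3)
  round_trip <- inverse_geometric(geometric_transform(z, resc), resc)
  expect_lt(max(abs(round_trip - z)), 1e-6)
  expect_error(geometric_transform(x, list(type = "rescale", factor = 1.5)),
               "integer")
  expect_error(geometric_transform(x, list(type = "shear")), "transform")
})

test_that("the segmentation encoder emits unit feature vectors on the input grid", {
  cfg <- tiny_cfg()
  wts <- withr::with_seed(4, semfuse:::seg_init(cfg))
  img <- rand_img(16, 16, seed = 5)
  z <- seg_forward(img, wts)
  expect_identical(dim(z), c(16L, 16L, cfg$semantic$feature_dim))
  norms <- sqrt(apply(z^2, c(1, 2), sum))
  expect_lt(max(abs(norms - 1)), 1e-5)
  expect_identical(z, seg_forward(img, wts))
  expect_error(seg_forward(rand_img(18, 18), wts), "divisible")
})

test_that("seeded k-means recovers structure and decreases its objective", {
  # single cluster: all labels 1, center is the mean
  x <- matrix(rnorm(40), 10, 4)
  k1 <- kmeans_unit(x, 1, seed = 1)
  expect_true(all(k1$labels == 1L))
  expect_equal(as.vector(k1$centers), colMeans(x), tolerance = 1e-12)
  expect_equal(as.vector(k1$centers_unit),
               colMeans(x) / sqrt(sum(colMeans(x)^2)), tolerance = 1e-12)
  # two tight antipodal blobs: exhaustive best 2-partition is the blobs
  base <- c(1, 0, 0)
  pts <- rbind(t(sapply(1:4, function(i) base + rnorm(3, sd = 0.01))),
               t(sapply(1:4, function(i) -base + rnorm(3, sd = 0.01))))
  pts <- pts / sqrt(rowSums(pts^2))
  km <- kmeans_unit(pts, 2, seed = 3)
  expect_identical(km$labels[1:4], rep(km$labels[1], 4))
  expect_identical(km$labels[5:8], rep(km$labels[5], 4))
  expect_false(km$labels[1] == km$labels[5])
  # exhaustive check: no labeling has a lower objective
  obj_of <- function(lab) {
    s <- 0
    for (j in 1:2) {
      idx <- lab == j
      if (!any(idx)) next
      mu <- colMeans(pts[idx, , drop = FALSE])
      s <- s + sum(sweep(pts[idx, , drop = FALSE], 2, mu)^2)
    }
    s
  }
  best <- min(vapply(0:(2^8 - 1), function(m)
    obj_of(as.integer(intToBits(m))[1:8] + 1L), numeric(1)))
  expect_equal(tail(km$objective, 1), best, tolerance = 1e-9)
  # monotone objective and determinism
  expect_true(all(diff(km$objective) <= 1e-12))
  expect_identical(km$labels, kmeans_unit(pts, 2, seed = 3)$labels)
})

test_that("k-means agrees with the stats::kmeans oracle on separated data", {
  set.seed(9)
  pts <- rbind(matrix(rnorm(30, mean = 3, sd = 0.1), 10, 3),
               matrix(rnorm(30, mean = -3, sd = 0.1), 10, 3))
  km <- kmeans_unit(pts, 2, seed = 2)
  ref <- stats::kmeans(pts, 2, nstart = 5)
  expect_equal(sort(table(km$labels)), sort(table(ref$cluster)),
               ignore_attr = TRUE)
  expect_equal(tail(km$objective, 1), ref$tot.withinss, tolerance = 1e-8)
})

test_that("cluster views are seeded and unit-normalized", {
  z1 <- rand_feat(4, 4, 6, seed = 6)
  z2 <- rand_feat(4, 4, 6, seed = 7)
  cs <- cluster_views(z1, z2, 3, seed = 11)
  expect_identical(cs$labels1, cluster_views(z1, z2, 3, seed = 11)$labels1)
  expect_lt(max(abs(sqrt(rowSums(cs$centers1^2)) - 1)), 1e-10)
  expect_true(all(cs$labels1 >= 1 & cs$labels1 <= 3))
  expect_error(cluster_views(z1, z2, 100, seed = 1), "exceeds")
})

test_that("clustering loss matches hand evaluations and decreases toward the center", {
  mu <- rbind(c(1, 0), c(-1, 0))
  expect_equal(clust_loss(c(1, 0), 1L, matrix(c(1, 0), 1)), 0)
  expect_equal(clust_loss(c(1, 0), 1L, mu), -log(1 / (1 + exp(-2))))
  angles <- seq(1.4, 0.1, by = -0.2)
  vals <- vapply(angles, function(a)
    clust_loss(c(cos(a), sin(a)), 1L, mu), numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_error(clust_loss(c(1, 0), 3L, mu), "label")
})

test_that("semantic loss honours its degeneracies and matches a scalar re-evaluation", {
  cfg <- tiny_cfg()
  wts <- withr::with_seed(8, semfuse:::seg_init(cfg))
  img <- small_pair(seed = 9, size = 32L)$image_b[1:16, 1:16]
  # K = 1: exactly zero
  r1 <- semantic_loss(img, wts, K = 1, seed = 4, config = cfg)
  expect_equal(r1$total, 0, tolerance = 1e-12)
  # identical transforms on both views: within and cross terms coincide
  cfg0 <- tiny_cfg(semantic = list(jitter = list(brightness = 0, contrast = 0,
                                                 gamma = 0), geo = "identity"))
  two_tone <- cbind(matrix(0.05, 16, 8), matrix(0.95, 16, 8))
  r2 <- semantic_loss(two_tone, wts, K = 2, seed = 5, config = cfg0)
  expect_equal(r2$within, r2$cross, tolerance = 1e-9)
  expect_equal(r2$total, r2$within + r2$cross, tolerance = 1e-12)
  # scalar re-evaluation from the returned clustering
  z1 <- seg_forward(semfuse:::ad_value(semfuse:::photo_node(
    semfuse:::ad_node(semfuse:::as_hwc(two_tone)),
    list(contrast = 1, brightness = 0, gamma = 1)))[, , 1], wts)
  zm <- matrix(z1, 256, cfg$semantic$feature_dim)
  cs <- r2$clusters
  manual1 <- mean(vapply(seq_len(nrow(zm)), function(i)
    clust_loss(zm[i, ], cs$labels1[i], cs$centers1), numeric(1)))
  manual2 <- mean(vapply(seq_len(nrow(zm)), function(i)
    clust_loss(zm[i, ], cs$labels2[i], cs$centers2), numeric(1)))
  expect_equal(r2$within, manual1 + manual2, tolerance = 1e-8)
  manual_cross <- mean(vapply(seq_len(nrow(zm)), function(i)
    clust_loss(zm[i, ], cs$labels2[i], cs$centers2), numeric(1))) +
    mean(vapply(seq_len(nrow(zm)), function(i)
      clust_loss(zm[i, ], cs$labels1[i], cs$centers1), numeric(1)))
  expect_equal(r2$cross, manual_cross, tolerance = 1e-8)
})

test_that("semantic loss is non-negative and the gradient reaches the image", {
  cfg <- tiny_cfg()
  wts <- withr::with_seed(10, semfuse:::seg_init(cfg))
  img <- small_pair(seed = 13, size = 32L)$image_b[1:16, 1:16]
  r <- semantic_loss(img, wts, K = 3, seed = 6, config = cfg)
  expect_gte(r$total, 0)
  node <- semfuse:::ad_leaf(semfuse:::as_hwc(img))
  res <- semfuse:::semantic_loss_node(list(node), wts, cfg, seed = 6)
  semfuse:::ad_backward(res$total)
  expect_gt(max(abs(semfuse:::ad_grad(node))), 0)
})

test_that("labels transport like the image under a flip for equivariant features", {
  # hand-built flip-equivariant field: two well-separated populations that
  # depend only on the distance of the column from the image center
  H <- 8L; W <- 8L
  inner <- abs(matrix(seq_len(W), H, W, byrow = TRUE) - (W + 1) / 2) < W / 4
  z <- array(0, c(H, W, 2))
  z[, , 1] <- ifelse(inner, 1, -1) + rand_img(H, W, seed = 21) * 0.01
  z[, , 2] <- ifelse(inner, -1, 1) + rand_img(H, W, seed = 22) * 0.01
  flip <- list(type = "hflip")
  zf <- geometric_transform(z, flip)
  cs <- cluster_views(z, zf, 2, seed = 3)
  flipped_lab1 <- matrix(cs$labels1, H, W)[, W:1]
  lab2 <- matrix(cs$labels2, H, W)
  agree <- max(mean(flipped_lab1 == lab2), mean(flipped_lab1 == 3L - lab2))
  expect_equal(agree, 1)
})
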