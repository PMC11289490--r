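# Unsupervised per-pixel segmentation providing the semantic loss.
#
# Two photometrically jittered views of each fused image (one additionally
# geometrically transformed and aligned back) pass through a small
# convolutional encoder producing a unit feature vector per pixel. Pixels
# of each view are clustered independently (seeded k-means on the pooled
# batch); the cluster assignments act as pseudo-labels. The semantic loss
# is the within-view clustering negative log-likelihood plus the
# cross-view term that scores each view against the other view's labels
# and centers. Labels and centers are constants within a step
# (stop-gradient); gradients reach the weights only through the features.

# ---- photometric jitter -------------------------------------------------

check_jitter <- function(jitter) {
  if (any(unlist(jitter) < 0) || jitter$contrast >= 1 || jitter$gamma >= 1)
    stop_config("jitter bounds must satisfy 0 <= brightness, 0 <= contrast < 1, 0 <= gamma < 1")
  jitter
}

draw_photo_params <- function(jitter) {
  list(contrast = stats::runif(1, 1 - jitter$contrast, 1 + jitter$contrast),
       brightness = stats::runif(1, -jitter$brightness, jitter$brightness),
       gamma = stats::runif(1, 1 - jitter$gamma, 1 + jitter$gamma))
}

photo_node <- function(x, p) {
  ad_pow_const(ad_clip01(ad_shift(ad_scale(ad_shift(x, -0.5), p$contrast),
                                  0.5 + p$brightness)), p$gamma)
}

#' Random photometric transform
#'
#' Seeded brightness / contrast / gamma jitter within the configured
#' bounds; all three component maps are monotone so pixel rank order is
#' preserved (up to clipping ties). Output is clipped to \[0,1\].
#'
#' @param image matrix in \[0,1\].
#' @param seed integer seed; identical seeds give identical outputs.
#' @param jitter list with `brightness`, `contrast`, `gamma` half-widths
#'   (contrast and gamma must be < 1).
#' @export
photometric_transform <- function(image, seed,
                                  jitter = list(brightness = 0.08,
                                                contrast = 0.1, gamma = 0.1)) {
  check_jitter(jitter)
  p <- with_seed(seed, draw_photo_params(jitter))
  ad_value(photo_node(ad_node(as_hwc(image)), p))[, , 1L]
}

# ---- geometric transforms ----------------------------------------------

check_geo <- function(params) {
  if (!params$type %in% c("identity", "hflip", "rescale"))
    stop_config("geometric transform must be identity, hflip or rescale")
  if (params$type == "rescale" &&
      (!is_count(params$factor) || params$factor < 1))
    stop_config("rescale factor must be a positive integer")
  params
}

geo_node <- function(x, params) {
  switch(params$type,
         identity = x,
         hflip = ad_flip_w(x),
         rescale = ad_upsample_nearest(x, as.integer(params$factor)))
}

geo_node_inv <- function(x, params) {
  switch(params$type,
         identity = x,
         hflip = ad_flip_w(x),
         rescale = ad_downsample_take(x, as.integer(params$factor)))
}

#' Invertible geometric transform of an image, feature or label field
#'
#' Supported transforms: horizontal flip and nearest-neighbour rescaling
#' by an integer factor. `inverse_geometric()` undoes the transform
#' exactly on the pixel grid; label fields are transported by the same
#' index operations (nearest neighbour), so label counts are preserved
#' under flips.
#'
#' @param field H x W matrix or (H, W, C) array.
#' @param params list with `type` ("identity", "hflip" or "rescale") and,
#'   for rescale, integer `factor`.
#' @rdname geometric
#' @export
geometric_transform <- function(field, params) {
  check_geo(params)
  was_mat <- is.matrix(field)
  out <- ad_value(geo_node(ad_node(as_hwc(field)), params))
  if (was_mat) out <- out[, , 1L]
  if (is.integer(field)) storage.mode(out) <- "integer"
  out
}

#' @rdname geometric
#' @export
inverse_geometric <- function(field, params) {
  check_geo(params)
  was_mat <- is.matrix(field)
  out <- ad_value(geo_node_inv(ad_node(as_hwc(field)), params))
  if (was_mat) out <- out[, , 1L]
  if (is.integer(field)) storage.mode(out) <- "integer"
  out
}

# ---- segmentation encoder ----------------------------------------------

seg_init <- function(cfg) {
  w <- as.integer(cfg$semantic$width)
  D <- as.integer(cfg$semantic$feature_dim)
  list(c1 = conv_init(3L, 1L, w),
       c2 = conv_init(3L, w, 2L * w),
       c3 = conv_init(3L, 2L * w, 2L * w),
       c4 = conv_init(3L, 2L * w, 2L * w),
       proj = conv_init(3L, 2L * w, D))
}

seg_fwd <- function(x, wts, slope = 0.01) {
  d <- dim(ad_value(x))
  f <- ad_leaky_relu(conv_fwd(x, wts$c1), slope)
  f <- ad_leaky_relu(conv_fwd(f, wts$c2, stride = 2L), slope)
  f <- ad_leaky_relu(conv_fwd(f, wts$c3), slope)
  f <- ad_leaky_relu(conv_fwd(f, wts$c4, stride = 2L), slope)
  f <- ad_upsample_bilinear(f, d[1L], d[2L])
  ad_l2norm_c(conv_fwd(f, wts$proj))
}

#' Per-pixel segmentation features
#'
#' Runs the segmentation encoder (two stride-2 downsamplings, bilinear
#' upsampling back to the input grid) and returns one unit-norm feature
#' vector per pixel.
#'
#' @param image H x W matrix, both sides divisible by 4.
#' @param weights segmentation weights ([seg_init] shape).
#' @param slope LeakyReLU negative slope.
#' @return (H, W, D) array with unit-norm channel fibres.
#' @export
seg_forward <- function(image, weights, slope = 0.01) {
  if (nrow(image) %% 4L != 0L || ncol(image) %% 4L != 0L)
    stop("seg_forward: image size must be divisible by 4")
  ad_value(seg_fwd(ad_node(as_hwc(image)), weights, slope))
}

# ---- k-means on unit vectors -------------------------------------------

#' Seeded k-means (k-means++ initialization, Lloyd iterations)
#'
#' Minimizes the within-cluster sum of squared Euclidean distances; the
#' objective is non-increasing across iterations (recorded in
#' `$objective`). Empty clusters are reseeded on the point farthest from
#' its center. `$centers_unit` holds the centers renormalized to unit
#' length for use with cosine-distance losses.
#'
#' @param x N x D matrix of observations (rows).
#' @param k number of clusters, 1 <= k <= N.
#' @param iters Lloyd iterations.
#' @param seed integer seed for initialization.
#' @return list with `labels` (length N, in 1..k), `centers` (k x D),
#'   `centers_unit`, `objective` (per-iteration values).
#' @export
kmeans_unit <- function(x, k, iters = 10L, seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (!is_count(k) || k < 1L) stop_config("k must be >= 1")
  if (k > n) stop_config("k (%d) exceeds number of points (%d)", k, n)
  with_seed(seed, {
    # k-means++ seeding
    centers <- matrix(0, k, ncol(x))
    centers[1L, ] <- x[sample.int(n, 1L), ]
    if (k > 1L) {
      d2 <- rowSums((x - matrix(centers[1L, ], n, ncol(x), byrow = TRUE))^2)
      for (j in 2:k) {
        pr <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
        centers[j, ] <- x[sample.int(n, 1L, prob = pr), ]
        d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x), byrow = TRUE))^2))
      }
    }
    obj <- numeric(0)
    labels <- rep(1L, n)
    for (it in seq_len(iters)) {
      # assign
      cross <- x %*% t(centers)
      cn <- rowSums(centers^2)
      d2m <- outer(rowSums(x^2), rep(1, k)) - 2 * cross +
        matrix(cn, n, k, byrow = TRUE)
      labels <- max.col(-d2m, ties.method = "first")
      obj <- c(obj, sum(d2m[cbind(seq_len(n), labels)]))
      # update
      for (j in seq_len(k)) {
        idx <- labels == j
        if (!any(idx)) {
          far <- which.max(d2m[cbind(seq_len(n), labels)])
          centers[j, ] <- x[far, ]
        } else {
          centers[j, ] <- colMeans(x[idx, , drop = FALSE])
        }
      }
    }
    cross <- x %*% t(centers)
    d2m <- outer(rowSums(x^2), rep(1, k)) - 2 * cross +
      matrix(rowSums(centers^2), n, k, byrow = TRUE)
    labels <- max.col(-d2m, ties.method = "first")
    obj <- c(obj, sum(d2m[cbind(seq_len(n), labels)]))
    nrm <- sqrt(rowSums(centers^2))
    nrm[nrm == 0] <- 1
    list(labels = labels, centers = centers, centers_unit = centers / nrm,
         objective = obj)
  })
}

#' Cluster the two feature views independently
#'
#' @param z1,z2 feature fields ((H, W, D) arrays, N x D matrices, or lists
#'   of either, pooled over the batch).
#' @param k cluster count.
#' @param seed integer seed (the second view uses `seed + 1`).
#' @param iters Lloyd iterations.
#' @return list of class `cluster_state` with per-view `labels` and unit
#'   `centers`.
#' @export
cluster_views <- function(z1, z2, k, seed = 1L, iters = 10L) {
  pool <- function(z) {
    if (is.list(z)) do.call(rbind, lapply(z, pool))
    else if (length(dim(z)) == 3L) matrix(z, prod(dim(z)[1:2]), dim(z)[3L])
    else as.matrix(z)
  }
  k1 <- kmeans_unit(pool(z1), k, iters, seed)
  k2 <- kmeans_unit(pool(z2), k, iters, seed + 1L)
  structure(list(labels1 = k1$labels, labels2 = k2$labels,
                 centers1 = k1$centers_unit, centers2 = k2$centers_unit,
                 k = k, objective1 = k1$objective, objective2 = k2$objective),
            class = "cluster_state")
}

#' Clustering negative log-likelihood for one feature vector
#'
#' `-log( exp(-d(z, mu_y)) / sum_l exp(-d(z, mu_l)) )` with `d` the cosine
#' distance `1 - <z, mu>`; always >= 0 and exactly 0 when there is a
#' single cluster.
#'
#' @param z unit feature vector (length D).
#' @param y assigned label in 1..K.
#' @param centers K x D matrix of unit cluster centers.
#' @export
clust_loss <- function(z, y, centers) {
  centers <- as.matrix(centers)
  if (!is_count(y) || y < 1L || y > nrow(centers))
    stop("clust_loss: label out of range")
  d <- 1 - as.vector(centers %*% z)
  m <- min(d)
  d[y] + log(sum(exp(-(d - m)))) - m
}

# ---- semantic loss ------------------------------------------------------

# node version over a batch of fused-image nodes; seg weights may be
# wrapped (trainable) or plain (frozen). Returns nodes and diagnostics.
# `clusters` may supply a frozen cluster state (pseudo-labels and centers
# are stop-gradient constants within a step; passing the state explicitly
# evaluates the same objective at a fixed clustering).
semantic_loss_node <- function(fused_nodes, seg_wts, cfg, seed,
                               slope = 0.01, clusters = NULL) {
  K <- as.integer(cfg$semantic$K)
  jitter <- check_jitter(cfg$semantic$jitter)
  geo_choices <- cfg$semantic$geo
  nb <- length(fused_nodes)
  z1 <- vector("list", nb)
  z2 <- vector("list", nb)
  with_seed(seed, {
    for (i in seq_len(nb)) {
      p1 <- draw_photo_params(jitter)
      p2 <- draw_photo_params(jitter)
      geo <- list(type = if (identical(geo_choices, "none")) "identity" else
        sample(c("identity", geo_choices), 1L))
      v1 <- photo_node(fused_nodes[[i]], p1)
      v2 <- geo_node(photo_node(fused_nodes[[i]], p2), check_geo(geo))
      z1[[i]] <- seg_fwd(v1, seg_wts, slope)
      z2[[i]] <- geo_node_inv(seg_fwd(v2, seg_wts, slope), geo)
    }
  })
  zmat <- function(zn) {
    d <- dim(ad_value(zn))
    ad_reshape(zn, c(d[1L] * d[2L], d[3L]))
  }
  cs <- if (is.null(clusters))
    cluster_views(lapply(z1, ad_value), lapply(z2, ad_value), K,
                  seed = seed, iters = cfg$semantic$kmeans_iters)
  else clusters
  npix <- vapply(z1, function(z) prod(dim(ad_value(z))[1:2]), numeric(1))
  offs <- cumsum(c(0, npix))
  nll <- function(zn, labels, centers) {
    dist <- ad_shift(ad_scale(ad_matmul(zmat(zn), t(centers)), -1), 1)
    ad_clust_nll(dist, labels)
  }
  terms_w <- list(); terms_c <- list()
  for (i in seq_len(nb)) {
    rows <- (offs[i] + 1L):offs[i + 1L]
    terms_w[[length(terms_w) + 1L]] <- nll(z1[[i]], cs$labels1[rows], cs$centers1)
    terms_w[[length(terms_w) + 1L]] <- nll(z2[[i]], cs$labels2[rows], cs$centers2)
    terms_c[[length(terms_c) + 1L]] <- nll(z1[[i]], cs$labels2[rows], cs$centers2)
    terms_c[[length(terms_c) + 1L]] <- nll(z2[[i]], cs$labels1[rows], cs$centers1)
  }
  avg <- function(terms) {
    s <- terms[[1L]]
    if (length(terms) > 1L) for (t in terms[-1L]) s <- ad_add(s, t)
    ad_scale(s, 2 / length(terms))  # sum of the two per-view means
  }
  within <- avg(terms_w)
  cross <- avg(terms_c)
  list(total = ad_add(within, cross), within = within, cross = cross,
       clusters = cs)
}

#' Semantic loss of a batch of fused images
#'
#' Builds two photometrically jittered views per image (the second also
#' geometrically transformed and aligned back), extracts per-pixel unit
#' features, clusters each view independently over the pooled batch, and
#' returns the within-view plus cross-view clustering losses averaged per
#' pixel. Zero when `K = 1`.
#'
#' @param fused_batch a matrix or list of matrices in \[0,1\].
#' @param seg_weights segmentation weights ([seg_init] shape).
#' @param K cluster count.
#' @param seed integer seed covering jitter draws and k-means.
#' @param config a `semfuse_config` (jitter bounds, k-means schedule).
#' @return list with `total`, `within`, `cross`, `clusters`.
#' @export
semantic_loss <- function(fused_batch, seg_weights, K = 8L, seed = 1L,
                          config = fusion_config()) {
  if (is.matrix(fused_batch)) fused_batch <- list(fused_batch)
  if (!length(fused_batch)) stop_config("fused_batch must be non-empty")
  cfg <- config
  cfg$semantic$K <- as.integer(K)
  nodes <- lapply(fused_batch, function(m) ad_node(as_hwc(m)))
  res <- semantic_loss_node(nodes, seg_weights, cfg, seed,
                            slope = cfg$extract$leaky_slope)
  list(total = ad_value(res$total), within = ad_value(res$within),
       cross = ad_value(res$cross), clusters = res$clusters)
}
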