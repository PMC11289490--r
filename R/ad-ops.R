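# Differentiable operations. Each op takes nodes (or plain numerics, which
# are promoted to constant leaves), computes the forward value eagerly and
# records a backward closure. Feature maps are (H, W, C) arrays.

sum_to_scalar <- function(g) sum(g)

ad_add <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  la <- length(a$value); lb <- length(b$value)
  ad_node(a$value + b$value, list(a, b), function(g) {
    list(if (la == 1L && length(g) > 1L) sum(g) else g,
         if (lb == 1L && length(g) > 1L) sum(g) else g)
  })
}

ad_sub <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  la <- length(a$value); lb <- length(b$value)
  ad_node(a$value - b$value, list(a, b), function(g) {
    list(if (la == 1L && length(g) > 1L) sum(g) else g,
         if (lb == 1L && length(g) > 1L) sum(-g) else -g)
  })
}

ad_mul <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  av <- a$value; bv <- b$value
  ad_node(av * bv, list(a, b), function(g) {
    ga <- g * bv; gb <- g * av
    list(if (length(av) == 1L && length(ga) > 1L) sum(ga) else ga,
         if (length(bv) == 1L && length(gb) > 1L) sum(gb) else gb)
  })
}

ad_div <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  av <- a$value; bv <- b$value
  y <- av / bv
  ad_node(y, list(a, b), function(g) {
    ga <- g / bv; gb <- -g * y / bv
    list(if (length(av) == 1L && length(ga) > 1L) sum(ga) else ga,
         if (length(bv) == 1L && length(gb) > 1L) sum(gb) else gb)
  })
}

ad_scale <- function(x, k) {
  x <- as_ad(x)
  ad_node(x$value * k, list(x), function(g) list(g * k))
}

ad_shift <- function(x, c) {
  x <- as_ad(x)
  ad_node(x$value + c, list(x), function(g) list(g))
}

ad_sum <- function(x) {
  x <- as_ad(x)
  d <- dim(x$value) %||% length(x$value)
  ad_node(sum(x$value), list(x), function(g) list(array(g, d)))
}

ad_mean <- function(x) {
  x <- as_ad(x)
  n <- length(x$value)
  d <- dim(x$value) %||% n
  ad_node(mean(x$value), list(x), function(g) list(array(g / n, d)))
}

ad_abs <- function(x) {
  x <- as_ad(x)
  s <- sign(x$value)
  ad_node(abs(x$value), list(x), function(g) list(g * s))
}

ad_relu <- function(x) {
  x <- as_ad(x)
  m <- x$value > 0
  ad_node(x$value * m, list(x), function(g) list(g * m))
}

ad_leaky_relu <- function(x, slope = 0.01) {
  x <- as_ad(x)
  m <- ifelse(x$value > 0, 1, slope)
  ad_node(x$value * m, list(x), function(g) list(g * m))
}

ad_sigmoid <- function(x) {
  x <- as_ad(x)
  y <- 1 / (1 + exp(-x$value))
  ad_node(y, list(x), function(g) list(g * y * (1 - y)))
}

# h-swish: x * min(max(x + 3, 0), 6) / 6
ad_hswish <- function(x) {
  x <- as_ad(x)
  v <- x$value
  r6 <- pmin(pmax(v + 3, 0), 6)
  y <- v * r6 / 6
  dr <- ifelse(v > -3 & v < 3, 1, 0)
  ad_node(y, list(x), function(g) list(g * (r6 / 6 + v * dr / 6)))
}

ad_pow_const <- function(x, p, eps = 1e-8) {
  x <- as_ad(x)
  v <- pmax(x$value, eps)
  y <- v^p
  ad_node(y, list(x), function(g) list(g * p * v^(p - 1)))
}

# clamp to [0,1]; gradient passes where the input was strictly inside
ad_clip01 <- function(x) {
  x <- as_ad(x)
  v <- x$value
  m <- v > 0 & v < 1
  ad_node(pmin(pmax(v, 0), 1), list(x), function(g) list(g * m))
}

ad_max2 <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  m <- a$value >= b$value
  ad_node(pmax(a$value, b$value), list(a, b),
          function(g) list(g * m, g * !m))
}

#' 2-D convolution node
#' @param x node, (H, W, Cin) array value
#' @param w node, (k, k, Cin, Cout) weights
#' @param b node of length Cout, or NULL
#' @keywords internal
ad_conv2d <- function(x, w, b = NULL, stride = 1L, pad = NULL) {
  x <- as_ad(x); w <- as_ad(w)
  if (!is.null(b)) b <- as_ad(b)
  d <- dim(x$value)
  k <- dim(w$value)[1L]
  p <- if (is.null(pad)) (k - 1L) %/% 2L else pad
  fw <- conv2d_forward(x$value, w$value, if (is.null(b)) NULL else b$value,
                       stride = stride, p = p)
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  wv <- w$value
  ad_node(fw$value, parents, function(g) {
    bw <- conv2d_backward(g, fw$Xcol, wv, fw$geom, d[1L], d[2L], d[3L],
                          stride, p)
    if (is.null(b)) list(bw$dx, bw$dW) else list(bw$dx, bw$dW, bw$db)
  })
}

# depthwise convolution with a fixed constant kernel (not trained)
ad_dwconv_fixed <- function(x, kern) {
  x <- as_ad(x)
  d <- dim(x$value)
  ad_node(dwconv_num(x$value, kern), list(x),
          function(g) list(dwconv_num_t(g, kern, d[1L], d[2L])))
}

# batch (instance) normalization; stats is an environment with rm, rv
ad_bn <- function(x, gamma, beta, stats = NULL, training = TRUE,
                  eps = 1e-5, momentum = 0.1) {
  x <- as_ad(x); gamma <- as_ad(gamma); beta <- as_ad(beta)
  d <- dim(x$value)
  N <- d[1L] * d[2L]; C <- d[3L]
  xm <- matrix(x$value, N, C)
  if (training || is.null(stats)) {
    mu <- colMeans(xm)
    va <- colMeans(xm^2) - mu^2
    if (!is.null(stats)) {
      stats$rm <- (1 - momentum) * stats$rm + momentum * mu
      stats$rv <- (1 - momentum) * stats$rv + momentum * va
    }
  } else {
    mu <- stats$rm
    va <- stats$rv
  }
  istd <- 1 / sqrt(va + eps)
  xhat <- (xm - rep(mu, each = N)) * rep(istd, each = N)
  y <- xhat * rep(gamma$value, each = N) + rep(beta$value, each = N)
  use_batch <- training || is.null(stats)
  ad_node(array(y, d), list(x, gamma, beta), function(g) {
    gm <- matrix(g, N, C)
    dgamma <- colSums(gm * xhat)
    dbeta <- colSums(gm)
    dxhat <- gm * rep(gamma$value, each = N)
    if (use_batch) {
      dx <- rep(istd, each = N) *
        (dxhat - rep(colMeans(dxhat), each = N) -
           xhat * rep(colMeans(dxhat * xhat), each = N))
    } else {
      dx <- dxhat * rep(istd, each = N)
    }
    list(array(dx, d), dgamma, dbeta)
  })
}

bn_stats_new <- function(C) {
  e <- new.env(parent = emptyenv())
  e$rm <- numeric(C)
  e$rv <- rep(1, C)
  e
}

ad_concat_c <- function(xs) {
  xs <- lapply(xs, as_ad)
  ds <- lapply(xs, function(x) dim(x$value))
  Cs <- vapply(ds, function(d) d[3L], numeric(1))
  H <- ds[[1L]][1L]; W <- ds[[1L]][2L]
  out <- array(0, c(H, W, sum(Cs)))
  at <- 0L
  for (i in seq_along(xs)) {
    out[, , at + seq_len(Cs[i])] <- xs[[i]]$value
    at <- at + Cs[i]
  }
  ad_node(out, xs, function(g) {
    res <- vector("list", length(xs))
    at <- 0L
    for (i in seq_along(xs)) {
      res[[i]] <- g[, , at + seq_len(Cs[i]), drop = FALSE]
      at <- at + Cs[i]
    }
    res
  })
}

# global spatial pooling -> (1, 1, C)
ad_gpool_avg <- function(x) {
  x <- as_ad(x)
  d <- dim(x$value)
  N <- d[1L] * d[2L]
  v <- colMeans(matrix(x$value, N, d[3L]))
  ad_node(array(v, c(1L, 1L, d[3L])), list(x), function(g) {
    list(array(rep(as.vector(g) / N, each = N), d))
  })
}

ad_gpool_max <- function(x) {
  x <- as_ad(x)
  d <- dim(x$value)
  N <- d[1L] * d[2L]
  xm <- matrix(x$value, N, d[3L])
  am <- max.col(t(xm), ties.method = "first")
  v <- xm[cbind(am, seq_len(d[3L]))]
  ad_node(array(v, c(1L, 1L, d[3L])), list(x), function(g) {
    gx <- matrix(0, N, d[3L])
    gx[cbind(am, seq_len(d[3L]))] <- as.vector(g)
    list(array(gx, d))
  })
}

# column-direction average pooling: mean over rows -> (1, W, C)
ad_pool_rows <- function(x) {
  x <- as_ad(x)
  d <- dim(x$value)
  v <- apply(x$value, c(2L, 3L), mean)
  ad_node(array(v, c(1L, d[2L], d[3L])), list(x), function(g) {
    list(array(rep(g, each = d[1L]), d) / d[1L])
  })
}

# row-direction average pooling: mean over columns -> (H, 1, C)
ad_pool_cols <- function(x) {
  x <- as_ad(x)
  d <- dim(x$value)
  v <- apply(x$value, c(1L, 3L), mean)
  ad_node(array(v, c(d[1L], 1L, d[3L])), list(x), function(g) {
    gy <- array(0, d)
    for (ch in seq_len(d[3L])) gy[, , ch] <- matrix(g[, 1L, ch], d[1L], d[2L]) / d[2L]
    list(gy)
  })
}

# broadcast a (1,W,C), (H,1,C) or (1,1,C) mask to (H,W,C)
ad_expand <- function(x, H, W) {
  x <- as_ad(x)
  d <- dim(x$value)
  C <- d[3L]
  if (d[1L] == 1L && d[2L] == W) {
    y <- array(rep(x$value, each = H), c(H, W, C))
    ad_node(y, list(x), function(g)
      list(array(apply(g, c(2L, 3L), sum), c(1L, W, C))))
  } else if (d[2L] == 1L && d[1L] == H) {
    y <- array(0, c(H, W, C))
    for (ch in seq_len(C)) y[, , ch] <- matrix(x$value[, 1L, ch], H, W)
    ad_node(y, list(x), function(g)
      list(array(apply(g, c(1L, 3L), sum), c(H, 1L, C))))
  } else if (d[1L] == 1L && d[2L] == 1L) {
    y <- array(rep(as.vector(x$value), each = H * W), c(H, W, C))
    ad_node(y, list(x), function(g)
      list(array(colSums(matrix(g, H * W, C)), c(1L, 1L, C))))
  } else stop("ad_expand: unsupported shape")
}

ad_upsample_bilinear <- function(x, Hout, Wout) {
  x <- as_ad(x)
  d <- dim(x$value)
  A <- upsample_matrix(d[1L], Hout)
  B <- upsample_matrix(d[2L], Wout)
  ad_node(mat_sandwich(x$value, A, B), list(x), function(g) {
    list(mat_sandwich(g, t(A), t(B)))
  })
}

ad_flip_w <- function(x) {
  x <- as_ad(x)
  W <- dim(x$value)[2L]
  ad_node(x$value[, W:1L, , drop = FALSE], list(x),
          function(g) list(g[, W:1L, , drop = FALSE]))
}

# nearest-neighbour upscale by integer factor
ad_upsample_nearest <- function(x, f) {
  x <- as_ad(x)
  d <- dim(x$value)
  ri <- rep(seq_len(d[1L]), each = f)
  ci <- rep(seq_len(d[2L]), each = f)
  ad_node(x$value[ri, ci, , drop = FALSE], list(x), function(g) {
    gH <- rowsum(matrix(g, d[1L] * f, d[2L] * f * d[3L]), rep(seq_len(d[1L]), each = f))
    gHa <- aperm(array(gH, c(d[1L], d[2L] * f, d[3L])), c(2L, 1L, 3L))
    gW <- rowsum(matrix(gHa, d[2L] * f, d[1L] * d[3L]), rep(seq_len(d[2L]), each = f))
    list(aperm(array(gW, c(d[2L], d[1L], d[3L])), c(2L, 1L, 3L)))
  })
}

# inverse of nearest upscale: take every f-th sample
ad_downsample_take <- function(x, f) {
  x <- as_ad(x)
  d <- dim(x$value)
  ri <- seq.int(1L, d[1L], by = f)
  ci <- seq.int(1L, d[2L], by = f)
  ad_node(x$value[ri, ci, , drop = FALSE], list(x), function(g) {
    gx <- array(0, d)
    gx[ri, ci, ] <- g
    list(gx)
  })
}

ad_reshape <- function(x, dims) {
  x <- as_ad(x)
  d0 <- dim(x$value) %||% length(x$value)
  ad_node(array(x$value, dims), list(x), function(g) list(array(g, d0)))
}

ad_matmul <- function(x, w) {
  x <- as_ad(x); w <- as_ad(w)
  xv <- x$value; wv <- w$value
  ad_node(xv %*% wv, list(x, w), function(g) {
    list(tcrossprod(g, wv), crossprod(xv, g))
  })
}

# normalize feature vectors along the last (channel) dimension to unit L2
ad_l2norm_c <- function(x, eps = 1e-12) {
  x <- as_ad(x)
  d <- dim(x$value)
  N <- d[1L] * d[2L]
  xm <- matrix(x$value, N, d[3L])
  nrm <- sqrt(rowSums(xm^2) + eps)
  y <- xm / nrm
  ad_node(array(y, d), list(x), function(g) {
    gm <- matrix(g, N, d[3L])
    dot <- rowSums(gm * y)
    list(array((gm - y * dot) / nrm, d))
  })
}

# mean over rows of  d[i, y_i] + log sum_l exp(-d[i, l])  (the clustering
# negative log-likelihood with cosine distances d, labels y)
ad_clust_nll <- function(dist, labels) {
  dist <- as_ad(dist)
  dv <- dist$value
  n <- nrow(dv)
  e <- exp(-(dv - apply(dv, 1L, min)))  # shifted for stability
  p <- e / rowSums(e)                   # softmax(-d)
  ll <- dv[cbind(seq_len(n), labels)] +
    log(rowSums(exp(-dv + apply(dv, 1L, min)))) - apply(dv, 1L, min)
  ad_node(mean(ll), list(dist), function(g) {
    gd <- -p
    gd[cbind(seq_len(n), labels)] <- gd[cbind(seq_len(n), labels)] + 1
    list(g * gd / n)
  })
}
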