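# Scalar, loop-based reference implementations used as independent oracles.
# They share only the published definitions with the package code, never
# its vectorized kernels.

o_reflect <- function(i, n) {
  if (i < 1) 2 - i else if (i > n) 2 * n - i else i
}

o_as_hwc <- function(x) if (is.matrix(x)) array(x, c(dim(x), 1L)) else x

# plain loop convolution, reflect-101 padding
oracle_conv <- function(x, w, b = NULL, stride = 1L) {
  x <- o_as_hwc(x)
  k <- dim(w)[1L]; p <- (k - 1L) %/% 2L
  H <- dim(x)[1L]; W <- dim(x)[2L]; Cin <- dim(x)[3L]; Cout <- dim(w)[4L]
  Hout <- (H + 2L * p - k) %/% stride + 1L
  Wout <- (W + 2L * p - k) %/% stride + 1L
  y <- array(0, c(Hout, Wout, Cout))
  for (co in seq_len(Cout)) for (oi in seq_len(Hout)) for (oj in seq_len(Wout)) {
    s <- if (is.null(b)) 0 else b[co]
    i0 <- (oi - 1L) * stride - p
    j0 <- (oj - 1L) * stride - p
    for (ci in seq_len(Cin)) for (dh in seq_len(k)) for (dw in seq_len(k)) {
      s <- s + x[o_reflect(i0 + dh, H), o_reflect(j0 + dw, W), ci] * w[dh, dw, ci, co]
    }
    y[oi, oj, co] <- s
  }
  y
}

oracle_sobel <- function(x) {
  x <- o_as_hwc(x)
  kk <- sobel_kernels()
  C <- dim(x)[3L]
  out <- array(0, dim(x))
  for (ci in seq_len(C)) {
    xs <- x[, , ci, drop = FALSE]
    gx <- oracle_conv(xs, array(kk$kx, c(3, 3, 1, 1)))
    gy <- oracle_conv(xs, array(kk$ky, c(3, 3, 1, 1)))
    out[, , ci] <- abs(gx[, , 1]) + abs(gy[, , 1])
  }
  out
}

# eval-mode batch norm with freshly initialized statistics (mean 0, var 1)
oracle_bn_eval <- function(x, lay, eps = 1e-5) {
  d <- dim(x)
  y <- x
  for (ci in seq_len(d[3L]))
    y[, , ci] <- lay$gamma[ci] * (x[, , ci] - lay$stats$rm[ci]) /
      sqrt(lay$stats$rv[ci] + eps) + lay$beta[ci]
  y
}

o_sig <- function(z) 1 / (1 + exp(-z))
o_relu <- function(z) pmax(z, 0)
o_hswish <- function(z) z * pmin(pmax(z + 3, 0), 6) / 6

# cross-modal attention, Eq.4 composition evaluated step by step
oracle_cmam <- function(fa, fb, w) {
  na <- oracle_bn_eval(o_as_hwc(fa), w$bn_a)
  nb <- oracle_bn_eval(o_as_hwc(fb), w$bn_b)
  mask <- function(x, mw) o_sig(oracle_conv(o_relu(oracle_conv(x, mw$c1$w, mw$c1$b)),
                                            mw$c2$w, mw$c2$b))
  ma <- mask(na, w$mask_a)
  mb <- mask(nb, w$mask_b)
  mult <- 1 + ma + mb
  cat_ab <- array(0, c(dim(na)[1:2], 2L * dim(na)[3L]))
  cat_ab[, , seq_len(dim(na)[3L])] <- na * mult
  cat_ab[, , dim(na)[3L] + seq_len(dim(na)[3L])] <- nb * mult
  list(value = oracle_conv(cat_ab, w$reduce$w, w$reduce$b), mult = mult)
}

# cross-branch attention, Eq.5
oracle_cbam <- function(f, w) {
  f <- o_as_hwc(f)
  C <- dim(f)[3L]
  dmax <- apply(f, 3L, max)
  davg <- apply(f, 3L, mean)
  mlp <- function(d) {
    h <- o_relu(oracle_conv(array(d, c(1, 1, C)), w$mlp1$w, w$mlp1$b))
    o_sig(oracle_conv(h, w$mlp2$w, w$mlp2$b))[1, 1, ]
  }
  mmax <- mlp(dmax)
  mavg <- mlp(davg)
  y <- f
  for (ci in seq_len(C)) y[, , ci] <- f[, , ci] * (1 + mmax[ci] + mavg[ci])
  list(value = oracle_bn_eval(oracle_conv(y, w$reduce$w, w$reduce$b), w$bn),
       mmax = mmax, mavg = mavg)
}

# cross-scale (coordinate) attention, Eq.6
oracle_csam <- function(f, w) {
  f <- o_as_hwc(f)
  H <- dim(f)[1L]; W <- dim(f)[2L]; C <- dim(f)[3L]
  xavg <- array(apply(f, c(2, 3), mean), c(1, W, C))
  yavg <- array(apply(f, c(1, 3), mean), c(H, 1, C))
  trunk <- function(strip) o_hswish(oracle_bn_eval(
    oracle_conv(strip, w$shared$w, w$shared$b), w$shared_bn))
  mx <- o_sig(oracle_conv(trunk(xavg), w$conv_x$w, w$conv_x$b))  # (1,W,C)
  my <- o_sig(oracle_conv(trunk(yavg), w$conv_y$w, w$conv_y$b))  # (H,1,C)
  y <- f
  for (ci in seq_len(C))
    y[, , ci] <- f[, , ci] *
      (1 + matrix(mx[1, , ci], H, W, byrow = TRUE) + matrix(my[, 1, ci], H, W))
  oracle_bn_eval(oracle_conv(y, w$reduce$w, w$reduce$b), w$bn)
}

# ---- metric oracles -----------------------------------------------------

oracle_ag <- function(img) {
  H <- nrow(img); W <- ncol(img)
  tot <- 0
  for (i in seq_len(H - 1)) for (j in seq_len(W - 1)) {
    dh <- img[i, j + 1] - img[i, j]
    dv <- img[i + 1, j] - img[i, j]
    tot <- tot + sqrt((dh^2 + dv^2) / 2)
  }
  tot / ((H - 1) * (W - 1))
}

oracle_sf <- function(img) {
  H <- nrow(img); W <- ncol(img)
  rf <- 0; cf <- 0
  for (i in seq_len(H)) for (j in 2:W) rf <- rf + (img[i, j] - img[i, j - 1])^2
  for (i in 2:H) for (j in seq_len(W)) cf <- cf + (img[i, j] - img[i - 1, j])^2
  sqrt(rf / (H * (W - 1)) + cf / ((H - 1) * W))
}

oracle_grad_ang <- function(img) {
  kk <- sobel_kernels()
  gx <- oracle_conv(img, array(kk$kx, c(3, 3, 1, 1)))[, , 1]
  gy <- oracle_conv(img, array(kk$ky, c(3, 3, 1, 1)))[, , 1]
  g <- sqrt(gx^2 + gy^2)
  a <- matrix(0, nrow(img), ncol(img))
  for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img))) {
    a[i, j] <- if (gx[i, j] == 0) {
      if (gy[i, j] == 0) 0 else sign(gy[i, j]) * pi / 2
    } else atan(gy[i, j] / gx[i, j])
  }
  list(g = g, a = a)
}

oracle_qpres <- function(gs, gf) {
  Tg <- 0.9994; kg <- -15; Dg <- 0.5
  Ta <- 0.9879; ka <- -22; Da <- 0.8
  H <- nrow(gs$g); W <- ncol(gs$g)
  q <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    gA <- gs$g[i, j]; gF <- gf$g[i, j]
    G <- if (gA > gF) { if (gA == 0) 0 else gF / gA } else { if (gF == 0) 0 else gA / gF }
    A <- 1 - abs(gs$a[i, j] - gf$a[i, j]) / (pi / 2)
    q[i, j] <- (Tg / (1 + exp(kg * (G - Dg)))) * (Ta / (1 + exp(ka * (A - Da))))
  }
  q
}

oracle_qabf <- function(fused, a, b) {
  ga <- oracle_grad_ang(a); gb <- oracle_grad_ang(b); gf <- oracle_grad_ang(fused)
  qa <- oracle_qpres(ga, gf); qb <- oracle_qpres(gb, gf)
  ws <- sum(ga$g) + sum(gb$g)
  if (ws == 0) return(0)
  sum(qa * ga$g + qb * gb$g) / ws
}

oracle_nabf <- function(fused, a, b) {
  ga <- oracle_grad_ang(a); gb <- oracle_grad_ang(b); gf <- oracle_grad_ang(fused)
  qa <- oracle_qpres(ga, gf); qb <- oracle_qpres(gb, gf)
  am <- gf$g > ga$g & gf$g > gb$g
  w <- ga$g + gb$g
  if (sum(w) > 0) return(sum(am * (1 - qa) * (1 - qb) * w) / sum(w))
  if (sum(gf$g) > 0) return(sum(am * (1 - qa) * (1 - qb) * gf$g) / sum(gf$g))
  0
}

# windowed SSIM by explicit window loops (reflect-padded Gaussian window)
oracle_ssim <- function(x, y, window = 11L, sigma = 1.5, L = 1) {
  H <- nrow(x); W <- ncol(x)
  n <- min(window, H - (1 - H %% 2L), W - (1 - W %% 2L))
  if (n %% 2L == 0L) n <- n - 1L
  r <- (n - 1L) / 2
  g1 <- exp(-((-r):r)^2 / (2 * sigma^2))
  win <- outer(g1, g1); win <- win / sum(win)
  c1 <- (0.01 * L)^2; c2 <- (0.03 * L)^2
  tot <- 0
  for (i in seq_len(H)) for (j in seq_len(W)) {
    sx <- 0; sy <- 0; sxx <- 0; syy <- 0; sxy <- 0
    for (di in (-r):r) for (dj in (-r):r) {
      wv <- win[di + r + 1, dj + r + 1]
      xv <- x[o_reflect(i + di, H), o_reflect(j + dj, W)]
      yv <- y[o_reflect(i + di, H), o_reflect(j + dj, W)]
      sx <- sx + wv * xv; sy <- sy + wv * yv
      sxx <- sxx + wv * xv^2; syy <- syy + wv * yv^2; sxy <- sxy + wv * xv * yv
    }
    vx <- sxx - sx^2; vy <- syy - sy^2; cxy <- sxy - sx * sy
    tot <- tot + ((2 * sx * sy + c1) * (2 * cxy + c2)) /
      ((sx^2 + sy^2 + c1) * (vx + vy + c2))
  }
  tot / (H * W)
}

# slow per-subband pixel-domain VIF
oracle_vif <- function(fused, reference, sigma_nsq = 2) {
  ref <- reference * 255; dis <- fused * 255
  gwin <- function(N) {
    r <- (N - 1) / 2
    g1 <- exp(-((-r):r)^2 / (2 * (N / 5)^2))
    k <- outer(g1, g1); k / sum(k)
  }
  cval <- function(x, win) {  # same-size filtering, reflect-101 border
    k <- nrow(win); r <- (k - 1) / 2
    H <- nrow(x); W <- ncol(x)
    y <- matrix(0, H, W)
    for (i in seq_len(H)) for (j in seq_len(W)) {
      s <- 0
      for (di in (-r):r) for (dj in (-r):r)
        s <- s + win[di + r + 1, dj + r + 1] *
          x[o_reflect(i + di, H), o_reflect(j + dj, W)]
      y[i, j] <- s
    }
    y
  }
  num <- 0; den <- 0; eps <- 1e-10
  for (scale in 1:4) {
    N <- 2^(4 - scale + 1) + 1
    win <- gwin(N)
    if (scale > 1) {
      ref <- cval(ref, win); dis <- cval(dis, win)
      ref <- ref[seq(1, nrow(ref), 2), seq(1, ncol(ref), 2), drop = FALSE]
      dis <- dis[seq(1, nrow(dis), 2), seq(1, ncol(dis), 2), drop = FALSE]
    }
    mu1 <- cval(ref, win); mu2 <- cval(dis, win)
    s1 <- pmax(cval(ref * ref, win) - mu1^2, 0)
    s2 <- pmax(cval(dis * dis, win) - mu2^2, 0)
    s12 <- cval(ref * dis, win) - mu1 * mu2
    g <- s12 / (s1 + eps)
    sv <- s2 - g * s12
    g[s1 < eps] <- 0; sv[s1 < eps] <- s2[s1 < eps]; s1[s1 < eps] <- 0
    g[s2 < eps] <- 0; sv[s2 < eps] <- 0
    sv[g < 0] <- s2[g < 0]; g[g < 0] <- 0
    sv[sv <= eps] <- eps
    num <- num + sum(log10(1 + g^2 * s1 / (sv + sigma_nsq)))
    den <- den + sum(log10(1 + s1 / sigma_nsq))
  }
  if (den == 0) 0 else num / den
}

# connected components (4-neighbour flood fill) of a logical mask
flood_count <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  seen <- matrix(FALSE, H, W)
  count <- 0L
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (!mask[i, j] || seen[i, j]) next
    count <- count + 1L
    queue <- list(c(i, j)); seen[i, j] <- TRUE
    while (length(queue)) {
      p <- queue[[length(queue)]]; queue[[length(queue)]] <- NULL
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        q <- p + d
        if (q[1] >= 1 && q[1] <= H && q[2] >= 1 && q[2] <= W &&
            mask[q[1], q[2]] && !seen[q[1], q[2]]) {
          seen[q[1], q[2]] <- TRUE
          queue[[length(queue) + 1L]] <- q
        }
      }
    }
  }
  count
}
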