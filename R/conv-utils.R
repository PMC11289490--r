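# Numeric 2-D convolution helpers shared by the autodiff ops and the plain
# numeric code paths (metrics, phantom texture). Feature maps are stored as
# (H, W, C) arrays; single-channel images as H x W matrices.

.conv_cache <- new.env(parent = emptyenv())

# reflect-101 index map: length H + 2p vector of source rows
reflect_index <- function(H, p) {
  if (p == 0L) return(seq_len(H))
  stopifnot(H > p)
  c((p + 1L):2L, seq_len(H), (H - 1L):(H - p))
}

as_hwc <- function(x) {
  if (is.matrix(x)) array(x, c(nrow(x), ncol(x), 1L)) else x
}

pad_reflect <- function(x, p) {
  if (p == 0L) return(x)
  x[reflect_index(dim(x)[1L], p), reflect_index(dim(x)[2L], p), , drop = FALSE]
}

# fold gradients on the reflect-padded array back onto the unpadded grid
# (rows first across every padded column, then columns, so corners count)
unpad_reflect_acc <- function(gxp, H, W, p) {
  if (p == 0L) return(gxp)
  g1 <- gxp[(p + 1L):(p + H), , , drop = FALSE]
  rmap <- reflect_index(H, p)
  for (j in seq_len(p)) {
    g1[rmap[j], , ] <- g1[rmap[j], , ] + gxp[j, , ]
    g1[rmap[p + H + j], , ] <- g1[rmap[p + H + j], , ] + gxp[p + H + j, , ]
  }
  g2 <- g1[, (p + 1L):(p + W), , drop = FALSE]
  cmap <- reflect_index(W, p)
  for (j in seq_len(p)) {
    g2[, cmap[j], ] <- g2[, cmap[j], ] + g1[, j, ]
    g2[, cmap[p + W + j], ] <- g2[, cmap[p + W + j], ] + g1[, p + W + j, ]
  }
  g2
}

# cached geometry for an im2col convolution
conv_geom <- function(H, W, Cin, k, stride, p) {
  key <- paste(H, W, Cin, k, stride, p, sep = "_")
  g <- .conv_cache[[key]]
  if (!is.null(g)) return(g)
  Hp <- H + 2L * p
  Wp <- W + 2L * p
  Hout <- (Hp - k) %/% stride + 1L
  Wout <- (Wp - k) %/% stride + 1L
  oh <- rep(seq.int(1L, by = stride, length.out = Hout), times = Wout)
  ow <- rep(seq.int(1L, by = stride, length.out = Wout), each = Hout)
  idx <- matrix(0L, Hout * Wout, k * k * Cin)
  col <- 1L
  for (ci in seq_len(Cin)) for (dw in 0:(k - 1L)) for (dh in 0:(k - 1L)) {
    idx[, col] <- (ci - 1L) * Hp * Wp + (ow + dw - 1L) * Hp + (oh + dh)
    col <- col + 1L
  }
  g <- list(
    Hp = Hp, Wp = Wp, Hout = Hout, Wout = Wout, idx = idx,
    oh0 = seq.int(1L, by = stride, length.out = Hout),
    ow0 = seq.int(1L, by = stride, length.out = Wout)
  )
  .conv_cache[[key]] <- g
  g
}

# forward im2col convolution; returns value plus the column matrix needed by
# the backward pass
conv2d_forward <- function(x, w, b = NULL, stride = 1L, p = 1L) {
  d <- dim(x)
  H <- d[1L]; W <- d[2L]; Cin <- d[3L]
  k <- dim(w)[1L]
  Cout <- dim(w)[4L]
  g <- conv_geom(H, W, Cin, k, stride, p)
  xp <- pad_reflect(x, p)
  # index with a plain vector: a matrix subscript whose column count equals
  # the array's dimension count would be read as coordinates
  Xcol <- matrix(xp[as.vector(g$idx)], nrow(g$idx))
  Wm <- matrix(w, k * k * Cin, Cout)
  Y <- Xcol %*% Wm
  if (!is.null(b)) Y <- Y + rep(b, each = nrow(Y))
  list(value = array(Y, c(g$Hout, g$Wout, Cout)), Xcol = Xcol, geom = g)
}

conv2d_backward <- function(grad, Xcol, w, g, H, W, Cin, stride, p) {
  k <- dim(w)[1L]
  Cout <- dim(w)[4L]
  dY <- matrix(grad, g$Hout * g$Wout, Cout)
  dW <- array(crossprod(Xcol, dY), dim(w))
  db <- colSums(dY)
  Wm <- matrix(w, k * k * Cin, Cout)
  dXcol <- tcrossprod(dY, Wm)
  gxp <- array(0, c(g$Hp, g$Wp, Cin))
  kk <- k * k
  for (off in seq_len(kk)) {
    dh <- (off - 1L) %% k
    dw_ <- (off - 1L) %/% k
    cols <- off + (seq_len(Cin) - 1L) * kk
    gxp[g$oh0 + dh, g$ow0 + dw_, ] <-
      gxp[g$oh0 + dh, g$ow0 + dw_, , drop = FALSE] +
      array(dXcol[, cols], c(g$Hout, g$Wout, Cin))
  }
  list(dx = unpad_reflect_acc(gxp, H, W, p), dW = dW, db = db)
}

# depthwise convolution with one fixed k x k kernel shared across channels
# (Sobel stencils, Gaussian windows); stride 1, reflect padding
dwconv_num <- function(x, kern) {
  x <- as_hwc(x)
  d <- dim(x)
  k <- nrow(kern)
  p <- (k - 1L) %/% 2L
  xp <- pad_reflect(x, p)
  y <- array(0, d)
  for (dh in 0:(k - 1L)) for (dw in 0:(k - 1L)) {
    kv <- kern[dh + 1L, dw + 1L]
    if (kv == 0) next
    y <- y + kv * xp[dh + seq_len(d[1L]), dw + seq_len(d[2L]), , drop = FALSE]
  }
  y
}

# transpose of dwconv_num (gradient with respect to its input)
dwconv_num_t <- function(grad, kern, H, W) {
  grad <- as_hwc(grad)
  k <- nrow(kern)
  p <- (k - 1L) %/% 2L
  C <- dim(grad)[3L]
  gxp <- array(0, c(H + 2L * p, W + 2L * p, C))
  for (dh in 0:(k - 1L)) for (dw in 0:(k - 1L)) {
    kv <- kern[dh + 1L, dw + 1L]
    if (kv == 0) next
    gxp[dh + seq_len(H), dw + seq_len(W), ] <-
      gxp[dh + seq_len(H), dw + seq_len(W), , drop = FALSE] + kv * grad
  }
  unpad_reflect_acc(gxp, H, W, p)
}

#' Sobel stencil pair
#'
#' The fixed 3x3 integer stencils for horizontal and vertical gradients.
#' Rows index the first image coordinate.
#'
#' @return list with elements `kx` and `ky`, each a 3x3 matrix.
#' @export
sobel_kernels <- function() {
  kx <- matrix(c(1, 0, -1, 2, 0, -2, 1, 0, -1), 3, 3)
  ky <- t(kx)
  list(kx = kx, ky = ky)
}

gaussian_kernel <- function(n, sigma) {
  stopifnot(n %% 2L == 1L)
  r <- (n - 1L) / 2
  g <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

# bilinear interpolation weight matrix Hin -> Hout (half-pixel centers)
upsample_matrix <- function(Hin, Hout) {
  key <- paste("up", Hin, Hout, sep = "_")
  A <- .conv_cache[[key]]
  if (!is.null(A)) return(A)
  A <- matrix(0, Hout, Hin)
  for (i in seq_len(Hout)) {
    src <- (i - 0.5) * Hin / Hout - 0.5
    i0 <- floor(src)
    w1 <- src - i0
    i0 <- min(max(i0, 0), Hin - 1)
    i1 <- min(i0 + 1, Hin - 1)
    A[i, i0 + 1] <- A[i, i0 + 1] + (1 - w1)
    A[i, i1 + 1] <- A[i, i1 + 1] + w1
  }
  .conv_cache[[key]] <- A
  A
}

# y[,,c] = A %*% x[,,c] %*% t(B) for all channels
mat_sandwich <- function(x, A, B) {
  d <- dim(x)
  t1 <- A %*% matrix(x, d[1L], d[2L] * d[3L])
  Hout <- nrow(A)
  t2 <- aperm(array(t1, c(Hout, d[2L], d[3L])), c(2L, 1L, 3L))
  t3 <- B %*% matrix(t2, d[2L], Hout * d[3L])
  aperm(array(t3, c(nrow(B), Hout, d[3L])), c(2L, 1L, 3L))
}
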