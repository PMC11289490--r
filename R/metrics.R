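# Fusion quality metrics: PSNR, average gradient, spatial frequency,
# gradient-based fusion performance (Qabf), fusion artifact measure
# (Nabf), pixel-domain visual information fidelity (VIF), SSIM and
# multi-scale SSIM. Two-reference metrics are aggregated over the two
# sources by mean (default) or max.

#' Peak signal-to-noise ratio
#'
#' `10 * log10(L^2 / MSE)`; `Inf` when the images are identical.
#'
#' @param fused,reference matrices of equal size.
#' @param L dynamic range (1 for \[0,1\] images).
#' @export
psnr <- function(fused, reference, L = 1) {
  check_same_shape(fused, reference)
  mse <- mean((fused - reference)^2)
  if (mse == 0) return(Inf)
  10 * log10(L^2 / mse)
}

#' Average gradient
#'
#' Mean over the forward-difference grid of
#' `sqrt((dh^2 + dv^2) / 2)`; describes image sharpness.
#'
#' @param image matrix, at least 2 x 2.
#' @export
average_gradient <- function(image) {
  H <- nrow(image); W <- ncol(image)
  if (H < 2L || W < 2L) stop("average_gradient: image must be >= 2x2")
  dh <- image[seq_len(H - 1L), -1L, drop = FALSE] -
    image[seq_len(H - 1L), -W, drop = FALSE]
  dv <- image[-1L, seq_len(W - 1L), drop = FALSE] -
    image[-H, seq_len(W - 1L), drop = FALSE]
  mean(sqrt((dh^2 + dv^2) / 2))
}

#' Spatial frequency
#'
#' `sqrt(RF^2 + CF^2)` with RF/CF the root-mean-square first differences
#' along rows and columns.
#'
#' @param image matrix, at least 2 x 2.
#' @export
spatial_frequency <- function(image) {
  H <- nrow(image); W <- ncol(image)
  if (H < 2L || W < 2L) stop("spatial_frequency: image must be >= 2x2")
  rf <- sqrt(mean((image[, -1L, drop = FALSE] - image[, -W, drop = FALSE])^2))
  cf <- sqrt(mean((image[-1L, , drop = FALSE] - image[-H, , drop = FALSE])^2))
  sqrt(rf^2 + cf^2)
}

# Sobel responses with reflect padding, plus strength and orientation
grad_strength_angle <- function(image) {
  kk <- sobel_kernels()
  gx <- dwconv_num(image, kk$kx)[, , 1L]
  gy <- dwconv_num(image, kk$ky)[, , 1L]
  g <- sqrt(gx^2 + gy^2)
  a <- atan(gy / gx)
  a[gx == 0 & gy == 0] <- 0
  a[gx == 0 & gy > 0] <- pi / 2
  a[gx == 0 & gy < 0] <- -pi / 2
  list(g = g, a = a)
}

# edge preservation estimate between one source and the fused image
edge_preservation <- function(src, fus) {
  Tg <- 0.9994; kg <- -15; Dg <- 0.5
  Ta <- 0.9879; ka <- -22; Da <- 0.8
  G <- ifelse(src$g > fus$g,
              ifelse(src$g == 0, 0, fus$g / src$g),
              ifelse(fus$g == 0, 0, src$g / fus$g))
  A <- 1 - abs(src$a - fus$a) / (pi / 2)
  Qg <- Tg / (1 + exp(kg * (G - Dg)))
  Qa <- Ta / (1 + exp(ka * (A - Da)))
  Qg * Qa
}

#' Gradient-based fusion performance (Qabf)
#'
#' Xydeas-Petrovic measure of how much source edge information (Sobel
#' strength and orientation) is preserved in the fused image, weighted by
#' source edge strength. 1 is perfect transfer; degenerate all-flat
#' inputs return 0.
#'
#' @param fused,a,b matrices of equal size.
#' @export
qabf <- function(fused, a, b) {
  check_same_shape(fused, a, b)
  ga <- grad_strength_angle(a)
  gb <- grad_strength_angle(b)
  gf <- grad_strength_angle(fused)
  qaf <- edge_preservation(ga, gf)
  qbf <- edge_preservation(gb, gf)
  wsum <- sum(ga$g) + sum(gb$g)
  if (wsum == 0) return(0)
  sum(qaf * ga$g + qbf * gb$g) / wsum
}

#' Fusion artifact measure (Nabf)
#'
#' Petrovic-style measure of gradient energy present in the fused image
#' but absent from both sources: over pixels where the fused edge strength
#' exceeds both source strengths, accumulates
#' `(1 - Q^{AF})(1 - Q^{BF})` weighted by source edge strength. When the
#' sources are entirely flat the artifact map is weighted by the fused
#' edge strength instead (pure invented noise); all-flat triples return 0.
#'
#' @inheritParams qabf
#' @export
nabf <- function(fused, a, b) {
  check_same_shape(fused, a, b)
  ga <- grad_strength_angle(a)
  gb <- grad_strength_angle(b)
  gf <- grad_strength_angle(fused)
  am <- gf$g > ga$g & gf$g > gb$g
  qaf <- edge_preservation(ga, gf)
  qbf <- edge_preservation(gb, gf)
  w <- ga$g + gb$g
  if (sum(w) > 0) return(sum(am * (1 - qaf) * (1 - qbf) * w) / sum(w))
  if (sum(gf$g) > 0) return(sum(am * (1 - qaf) * (1 - qbf) * gf$g) / sum(gf$g))
  0
}

#' Pixel-domain visual information fidelity
#'
#' Four-scale Gaussian scale-mixture variance partition in the pixel
#' domain (same-size reflect-padded filtering, dyadic subsampling between
#' scales); 1 when the fused image equals the reference, lower under
#' distortion such as blur.
#'
#' @param fused,reference matrices of equal size, at least 32 x 32.
#' @param sigma_nsq visual noise variance.
#' @export
vif <- function(fused, reference, sigma_nsq = 2) {
  check_same_shape(fused, reference)
  if (min(nrow(fused), ncol(fused)) < 32L) stop("vif: images must be >= 32x32")
  ref <- reference * 255
  dis <- fused * 255
  gfilt <- function(x, win) dwconv_num(x, win)[, , 1L]
  num <- 0; den <- 0
  eps <- 1e-10
  for (scale in 1:4) {
    N <- 2^(4 - scale + 1) + 1
    win <- gaussian_kernel(N, N / 5)
    if (scale > 1) {
      ref <- gfilt(ref, win)
      dis <- gfilt(dis, win)
      ref <- ref[seq.int(1L, nrow(ref), 2L), seq.int(1L, ncol(ref), 2L)]
      dis <- dis[seq.int(1L, nrow(dis), 2L), seq.int(1L, ncol(dis), 2L)]
    }
    mu1 <- gfilt(ref, win)
    mu2 <- gfilt(dis, win)
    s1 <- pmax(gfilt(ref * ref, win) - mu1^2, 0)
    s2 <- pmax(gfilt(dis * dis, win) - mu2^2, 0)
    s12 <- gfilt(ref * dis, win) - mu1 * mu2
    g <- s12 / (s1 + eps)
    sv <- s2 - g * s12
    g[s1 < eps] <- 0
    sv[s1 < eps] <- s2[s1 < eps]
    s1[s1 < eps] <- 0
    g[s2 < eps] <- 0
    sv[s2 < eps] <- 0
    sv[g < 0] <- s2[g < 0]
    g[g < 0] <- 0
    sv[sv <= eps] <- eps
    num <- num + sum(log10(1 + g^2 * s1 / (sv + sigma_nsq)))
    den <- den + sum(log10(1 + s1 / sigma_nsq))
  }
  if (den == 0) return(0)
  num / den
}

ssim_components <- function(x, y, window = 11L, sigma = 1.5, L = 1) {
  d <- dim(as_hwc(x))
  win <- ssim_window(d[1L], d[2L], window, sigma)
  c1 <- (0.01 * L)^2
  c2 <- (0.03 * L)^2
  g <- function(z) dwconv_num(z, win)[, , 1L]
  mx <- g(x); my <- g(y)
  sx <- g(x * x) - mx^2
  sy <- g(y * y) - my^2
  sxy <- g(x * y) - mx * my
  cs <- (2 * sxy + c2) / (sx + sy + c2)
  lum <- (2 * mx * my + c1) / (mx^2 + my^2 + c1)
  list(ssim = mean(lum * cs), cs = mean(cs))
}

#' Multi-scale structural similarity
#'
#' Standard 5-level product with exponents
#' (0.0448, 0.2856, 0.3001, 0.2363, 0.1333); each level halves resolution
#' by 2 x 2 average pooling. With `levels = 1` this reduces to single-scale
#' [ssim()].
#'
#' @param x,y matrices of equal size; the default 5 levels require at
#'   least 16 x 16.
#' @param levels number of dyadic levels.
#' @inheritParams ssim
#' @export
msssim <- function(x, y, levels = 5L, window = 11L, sigma = 1.5, L = 1) {
  check_same_shape(x, y)
  if (min(nrow(x), ncol(x)) < 2^(levels - 1L))
    stop("msssim: image too small for the requested number of levels")
  if (levels == 1L) return(ssim(x, y, window, sigma, L))
  wts <- c(0.0448, 0.2856, 0.3001, 0.2363, 0.1333)[seq_len(levels)]
  down2 <- function(m) {
    H <- 2L * (nrow(m) %/% 2L); W <- 2L * (ncol(m) %/% 2L)
    m <- m[seq_len(H), seq_len(W), drop = FALSE]
    0.25 * (m[seq.int(1L, H, 2L), seq.int(1L, W, 2L)] +
              m[seq.int(2L, H, 2L), seq.int(1L, W, 2L)] +
              m[seq.int(1L, H, 2L), seq.int(2L, W, 2L)] +
              m[seq.int(2L, H, 2L), seq.int(2L, W, 2L)])
  }
  val <- 1
  for (l in seq_len(levels)) {
    comp <- ssim_components(x, y, window, sigma, L)
    if (l < levels) {
      val <- val * max(comp$cs, 0)^wts[l]
      x <- down2(x)
      y <- down2(y)
    } else {
      val <- val * max(comp$ssim, 0)^wts[l]
    }
  }
  val
}

#' Evaluate all eight fusion metrics on one triple
#'
#' PSNR, SSIM, MS-SSIM and VIF are computed against each source and
#' aggregated (`mode`); AG and SF are computed on the fused image alone;
#' Qabf and Nabf use the full triple.
#'
#' @param fused,a,b matrices of equal size.
#' @param mode aggregation over the two sources: "mean" or "max".
#' @return list of class `metric_report` with the eight fields.
#' @export
evaluate_all <- function(fused, a, b, mode = c("mean", "max")) {
  mode <- match.arg(mode)
  check_same_shape(fused, a, b)
  agg <- function(u, v) if (mode == "mean") (u + v) / 2 else max(u, v)
  structure(list(
    psnr = agg(psnr(fused, a), psnr(fused, b)),
    vif = agg(vif(fused, a), vif(fused, b)),
    ag = average_gradient(fused),
    qabf = qabf(fused, a, b),
    sf = spatial_frequency(fused),
    nabf = nabf(fused, a, b),
    ssim = agg(ssim(fused, a), ssim(fused, b)),
    msssim = agg(msssim(fused, a), msssim(fused, b))
  ), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("psnr %.3f  vif %.4f  ag %.4f  qabf %.4f  sf %.4f  nabf %.4f  ssim %.4f  msssim %.4f\n",
              x$psnr, x$vif, x$ag, x$qabf, x$sf, x$nabf, x$ssim, x$msssim))
  invisible(x)
}

#' Evaluate a batch and assemble the report table
#'
#' @param fused_list,a_list,b_list lists of matrices.
#' @param ids identifiers, one per triple.
#' @param mode aggregation over sources.
#' @param path optional CSV output path (columns: id, psnr, vif, ag,
#'   qabf, sf, nabf, ssim, msssim).
#' @return data.frame, one row per triple.
#' @export
evaluate_batch <- function(fused_list, a_list, b_list,
                           ids = seq_along(fused_list),
                           mode = "mean", path = NULL) {
  rows <- lapply(seq_along(fused_list), function(i) {
    r <- evaluate_all(fused_list[[i]], a_list[[i]], b_list[[i]], mode)
    data.frame(id = ids[i], psnr = r$psnr, vif = r$vif, ag = r$ag,
               qabf = r$qabf, sf = r$sf, nabf = r$nabf, ssim = r$ssim,
               msssim = r$msssim, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
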