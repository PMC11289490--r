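# Fusion losses: content (intensity + alpha * texture), SSIM-based
# similarity, and the assembled total with the semantic term.
#
# Every public function accepts plain matrices and returns a scalar; the
# `_node` variants operate on autodiff nodes so the same definitions drive
# training gradients.

check_same_shape <- function(...) {
  ds <- lapply(list(...), function(x) dim(as_hwc(ad_value(x))))
  if (!all(vapply(ds, identical, logical(1), ds[[1L]])))
    stop("loss inputs must share dimensions")
}

intensity_loss_node <- function(i_f, target_max) {
  ad_mean(ad_abs(ad_sub(i_f, target_max)))
}

#' Intensity loss
#'
#' Mean absolute deviation of the fused image from the element-wise
#' maximum of the two sources: `(1/HW) * ||I_f - max(I_ct, I_mri)||_1`.
#'
#' @param i_f,i_ct,i_mri H x W matrices of equal size.
#' @return non-negative scalar; zero iff `i_f` equals the pixelwise max.
#' @export
intensity_loss <- function(i_f, i_ct, i_mri) {
  check_same_shape(i_f, i_ct, i_mri)
  mean(abs(i_f - pmax(i_ct, i_mri)))
}

texture_loss_node <- function(i_f, target_grad) {
  ad_mean(ad_abs(ad_sub(ad_sobel_mag(i_f), target_grad)))
}

#' Texture loss
#'
#' Mean absolute deviation between the Sobel gradient magnitude of the
#' fused image and the element-wise maximum of the source gradient
#' magnitudes: `(1/HW) * || |grad I_f| - max(|grad I_ct|, |grad I_mri|) ||_1`.
#'
#' @inheritParams intensity_loss
#' @return non-negative scalar.
#' @export
texture_loss <- function(i_f, i_ct, i_mri) {
  check_same_shape(i_f, i_ct, i_mri)
  if (nrow(i_f) < 3L || ncol(i_f) < 3L) stop("texture_loss: images must be >= 3x3")
  mean(abs(sobel_gradient(i_f) - pmax(sobel_gradient(i_ct), sobel_gradient(i_mri))))
}

#' Content loss
#'
#' `L_int + alpha * L_texture`; the balance constant defaults to 5.
#'
#' @inheritParams intensity_loss
#' @param alpha non-negative texture weight.
#' @export
content_loss <- function(i_f, i_ct, i_mri, alpha = 5) {
  if (alpha < 0) stop_config("alpha must be >= 0")
  intensity_loss(i_f, i_ct, i_mri) + alpha * texture_loss(i_f, i_ct, i_mri)
}

# ---- SSIM ---------------------------------------------------------------

ssim_window <- function(H, W, window, sigma) {
  n <- min(window, H - (1 - H %% 2L), W - (1 - W %% 2L))
  if (n %% 2L == 0L) n <- n - 1L
  n <- max(n, 1L)
  gaussian_kernel(n, sigma)
}

ssim_node <- function(x, y, window = 11L, sigma = 1.5, L = 1) {
  d <- dim(as_hwc(ad_value(x)))
  win <- ssim_window(d[1L], d[2L], window, sigma)
  c1 <- (0.01 * L)^2
  c2 <- (0.03 * L)^2
  g <- function(z) ad_dwconv_fixed(z, win)
  mx <- g(x); my <- g(y)
  mxy <- ad_mul(mx, my)
  mx2 <- ad_mul(mx, mx)
  my2 <- ad_mul(my, my)
  sx <- ad_sub(g(ad_mul(x, x)), mx2)
  sy <- ad_sub(g(ad_mul(y, y)), my2)
  sxy <- ad_sub(g(ad_mul(x, y)), mxy)
  num <- ad_mul(ad_shift(ad_scale(mxy, 2), c1), ad_shift(ad_scale(sxy, 2), c2))
  den <- ad_mul(ad_shift(ad_add(mx2, my2), c1), ad_shift(ad_add(sx, sy), c2))
  ad_mean(ad_div(num, den))
}

#' Structural similarity index
#'
#' Windowed SSIM with a Gaussian window (default 11 x 11, sigma 1.5,
#' shrunk to fit small images), averaged over all pixel-centred windows
#' with reflect padding. `ssim(x, x)` is 1; the value is symmetric and
#' lies in \[-1, 1\].
#'
#' @param x,y matrices of equal size.
#' @param window odd window side length.
#' @param sigma Gaussian window standard deviation.
#' @param L dynamic range of the data (1 for \[0,1\] images).
#' @export
ssim <- function(x, y, window = 11L, sigma = 1.5, L = 1) {
  check_same_shape(x, y)
  if (L <= 0) stop_config("L must be > 0")
  ad_value(ssim_node(ad_node(as_hwc(x)), ad_node(as_hwc(y)), window, sigma, L))
}

similarity_loss_node <- function(i_f, i_ct, i_mri, window = 11L, sigma = 1.5) {
  s <- ad_add(ssim_node(i_f, i_ct, window, sigma), ssim_node(i_f, i_mri, window, sigma))
  ad_shift(ad_scale(s, -0.5), 1)
}

#' Similarity loss
#'
#' `1 - (SSIM(I_f, I_ct) + SSIM(I_f, I_mri)) / 2`, in \[0, 2\].
#'
#' @inheritParams intensity_loss
#' @inheritParams ssim
#' @export
similarity_loss <- function(i_f, i_ct, i_mri, window = 11L, sigma = 1.5) {
  check_same_shape(i_f, i_ct, i_mri)
  1 - (ssim(i_f, i_ct, window, sigma) + ssim(i_f, i_mri, window, sigma)) / 2
}

#' Total fusion loss with component breakdown
#'
#' Assembles `L = L_content + L_similarity + L_semantic` with
#' `L_content = L_int + alpha * L_texture`. The semantic term is supplied
#' by the caller (see [semantic_loss()]).
#'
#' @inheritParams content_loss
#' @param semantic_value non-negative semantic loss value.
#' @return list of class `loss_breakdown` with fields `total`, `content`,
#'   `intensity`, `texture`, `alpha`, `similarity`, `semantic`.
#' @export
total_fusion_loss <- function(i_f, i_ct, i_mri, semantic_value = 0, alpha = 5) {
  if (semantic_value < 0) stop_config("semantic_value must be >= 0")
  li <- intensity_loss(i_f, i_ct, i_mri)
  lt <- texture_loss(i_f, i_ct, i_mri)
  ls <- similarity_loss(i_f, i_ct, i_mri)
  structure(list(total = li + alpha * lt + ls + semantic_value,
                 content = li + alpha * lt,
                 intensity = li, texture = lt, alpha = alpha,
                 similarity = ls, semantic = semantic_value),
            class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf(paste0("fusion loss %.5f = content %.5f (int %.5f + %g * tex %.5f)",
                     " + similarity %.5f + semantic %.5f\n"),
              x$total, x$content, x$intensity, x$alpha, x$texture,
              x$similarity, x$semantic))
  invisible(x)
}
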