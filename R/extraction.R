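# Multi-branch, multi-scale feature extraction.
#
# Each modality is processed by `extract.branches` identical (but
# independently parameterized) branches. A branch applies two stride-1
# convolutions (emitting the finest-scale features F_0) followed by one
# downsampling / non-downsampling pair of Sobel feature-extraction blocks
# per remaining scale, halving the spatial size once per pair.

#' Sobel gradient magnitude
#'
#' Applies the fixed 3x3 Sobel stencils depthwise (per channel) with
#' reflect padding and returns `|Dx * f| + |Dy * f|`, the sum of absolute
#' directional responses. Constant inputs map to zero; adding a constant
#' to the input leaves the output unchanged.
#'
#' @param x H x W matrix or (H, W, C) array, spatial size >= 3.
#' @return array of the same shape as `x` (matrices come back as matrices).
#' @export
sobel_gradient <- function(x) {
  was_mat <- is.matrix(x)
  x <- as_hwc(x)
  if (dim(x)[1L] < 3L || dim(x)[2L] < 3L)
    stop("sobel_gradient: spatial size must be >= 3")
  kk <- sobel_kernels()
  y <- abs(dwconv_num(x, kk$kx)) + abs(dwconv_num(x, kk$ky))
  if (was_mat) y[, , 1L] else y
}

# autodiff version used inside the network and the texture loss
ad_sobel_mag <- function(x) {
  kk <- sobel_kernels()
  ad_add(ad_abs(ad_dwconv_fixed(x, kk$kx)), ad_abs(ad_dwconv_fixed(x, kk$ky)))
}

# ---- feature extraction block (Fig-4-style) -----------------------------
# Two processing paths share the input: a plain convolution and a Sobel
# path of two stages (Sobel -> conv, then Sobel -> conv with a skip from
# the first stage); the three contributions are summed and passed through
# LeakyReLU. The downsampling variant strides its first-stage convolutions.

feb_init <- function(cin, cout, stride = 1L) {
  # stride stored as character so the parameter-tree walkers (which treat
  # every numeric leaf as trainable) pass it through untouched
  list(plain = conv_init(3L, cin, cout),
       sob1 = conv_init(3L, cin, cout),
       sob2 = conv_init(3L, cout, cout),
       stride = as.character(stride))
}

feb_fwd <- function(x, wts, slope = 0.01) {
  s <- as.integer(wts$stride)
  p <- conv_fwd(x, wts$plain, stride = s)
  s1 <- conv_fwd(ad_sobel_mag(x), wts$sob1, stride = s)
  s2 <- ad_add(conv_fwd(ad_sobel_mag(s1), wts$sob2), s1)
  ad_leaky_relu(ad_add(ad_add(p, s1), s2), slope)
}

#' Apply one Sobel feature-extraction block
#'
#' Plain-array wrapper around the block used inside every branch:
#' `LeakyReLU(plainConv(x) + sobelPath1(x) + sobelPath2(x))`, where the
#' second Sobel path carries a skip connection from the first.
#'
#' @param x (H, W, Cin) array.
#' @param weights block weights from an extractor (or [feb_init] shape).
#' @param slope LeakyReLU negative slope.
#' @return (H', W', Cout) array; spatial size preserved unless the block
#'   is a downsampling block.
#' @export
feature_extract_block <- function(x, weights, slope = 0.01) {
  x <- as_hwc(x)
  if (dim(x)[3L] != dim(weights$plain$w)[3L])
    stop("feature_extract_block: channel mismatch")
  ad_value(feb_fwd(ad_node(x), weights, slope))
}

# ---- one branch ---------------------------------------------------------

branch_init <- function(channels) {
  S <- length(channels)
  br <- list(conv0a = conv_init(3L, 1L, channels[1L]),
             conv0b = conv_init(3L, channels[1L], channels[1L]),
             pairs = list())
  if (S > 1L) for (i in 2:S) {
    br$pairs[[i - 1L]] <- list(
      down = feb_init(channels[i - 1L], channels[i], stride = 2L),
      keep = feb_init(channels[i], channels[i], stride = 1L))
  }
  br
}

branch_fwd <- function(x, br, slope = 0.01) {
  f <- ad_leaky_relu(conv_fwd(x, br$conv0a), slope)
  f0 <- ad_leaky_relu(conv_fwd(f, br$conv0b), slope)
  levels <- list(f0)
  f <- f0
  for (pair in br$pairs) {
    f <- feb_fwd(feb_fwd(f, pair$down, slope), pair$keep, slope)
    levels[[length(levels) + 1L]] <- f
  }
  levels
}

#' Run one extraction branch over an image
#'
#' @param image H x W matrix in \[0,1\]; spatial size must be divisible by
#'   `2^(n_scales - 1)`.
#' @param branch_weights one branch of an initialized extractor.
#' @param slope LeakyReLU negative slope.
#' @return list of feature arrays, finest to coarsest; level `i` has half
#'   the spatial size of level `i - 1`.
#' @export
branch_forward <- function(image, branch_weights, slope = 0.01) {
  S <- length(branch_weights$pairs) + 1L
  fac <- 2L^(S - 1L)
  if (nrow(image) %% fac != 0L || ncol(image) %% fac != 0L)
    stop(sprintf("branch_forward: image size must be divisible by %d", fac))
  lapply(branch_fwd(ad_node(as_hwc(image)), branch_weights, slope), ad_value)
}

# ---- extractor over both modalities ------------------------------------

extractor_init <- function(cfg) {
  ch <- as.integer(cfg$extract$channels)
  B <- cfg$extract$branches
  mk <- function() lapply(seq_len(B), function(i) branch_init(ch))
  a <- mk()
  b <- if (isTRUE(cfg$extract$share_modality)) a else mk()
  list(a = a, b = b)
}

extract_fwd <- function(xa, xb, ext, slope) {
  list(a = lapply(ext$a, function(br) branch_fwd(xa, br, slope)),
       b = lapply(ext$b, function(br) branch_fwd(xb, br, slope)))
}

#' Extract multi-branch multi-scale features from a registered pair
#'
#' @param pair a `registered_pair` (or list with `image_a`, `image_b` of
#'   equal size).
#' @param model a fitted or initialized model (see [semfuse()] /
#'   [init_model()]).
#' @return list with elements `a` and `b`, each a list of branch pyramids;
#'   each pyramid is a list of feature arrays, finest to coarsest.
#' @export
extract_all <- function(pair, model) {
  if (!identical(dim(pair$image_a), dim(pair$image_b)))
    stop("extract_all: images must be registered (equal size)")
  slope <- model$config$extract$leaky_slope
  fw <- extract_fwd(ad_node(as_hwc(pair$image_a)), ad_node(as_hwc(pair$image_b)),
                    model$fusion$ext, slope)
  list(a = lapply(fw$a, function(p) lapply(p, ad_value)),
       b = lapply(fw$b, function(p) lapply(p, ad_value)))
}
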