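# Attention-based fusion and reconstruction.
#
# Five fusion blocks run coarse-to-fine. In each block, per-branch
# cross-modal attention fuses the two modalities, cross-branch attention
# fuses the three branches, and (except at the coarsest scale, which has
# no upstream input) cross-scale attention fuses the upsampled output of
# the previous block with the current scale. Every attention multiplier is
# 1 + (sum of two sigmoid masks) and therefore lies strictly in (1, 3).

rec_mult <- function(rec, mult_node) {
  if (!is.null(rec)) rec$ranges[[length(rec$ranges) + 1L]] <- range(ad_value(mult_node))
  invisible(NULL)
}

# ---- cross-modal attention (two modalities, one branch) -----------------

cmam_init <- function(C, ratio, reduction_kernel = 1L, use_attention = TRUE) {
  Cr <- max(1L, C %/% ratio)
  w <- list(bn_a = bn_init(C), bn_b = bn_init(C),
            reduce = conv_init(reduction_kernel, 2L * C, C))
  if (use_attention) {
    w$mask_a <- list(c1 = conv_init(3L, C, Cr), c2 = conv_init(3L, Cr, C))
    w$mask_b <- list(c1 = conv_init(3L, C, Cr), c2 = conv_init(3L, Cr, C))
  }
  w
}

cmam_fwd <- function(fa, fb, w, training = FALSE, rec = NULL) {
  na <- bn_fwd(fa, w$bn_a, training)
  nb <- bn_fwd(fb, w$bn_b, training)
  if (!is.null(w$mask_a)) {
    ma <- ad_sigmoid(conv_fwd(ad_relu(conv_fwd(na, w$mask_a$c1)), w$mask_a$c2))
    mb <- ad_sigmoid(conv_fwd(ad_relu(conv_fwd(nb, w$mask_b$c1)), w$mask_b$c2))
    mult <- ad_shift(ad_add(ma, mb), 1)
    rec_mult(rec, mult)
    na <- ad_mul(na, mult)
    nb <- ad_mul(nb, mult)
  }
  conv_fwd(ad_concat_c(list(na, nb)), w$reduce)
}

#' Cross-modal attention fusion
#'
#' Normalizes the two modality features, builds one sigmoid mask from each
#' modality, rescales both features by `1 + M_own + M_cross`, concatenates
#' them and reduces back to the input width with a convolution.
#'
#' @param f_a,f_b (H, W, C) feature arrays of equal shape.
#' @param weights a [cmam_init] weight list.
#' @param training use batch statistics in the normalization layers.
#' @return fused (H, W, C) array with attribute `"multiplier"` holding the
#'   attention multiplier field.
#' @export
cross_modal_attention <- function(f_a, f_b, weights, training = FALSE) {
  f_a <- as_hwc(f_a); f_b <- as_hwc(f_b)
  if (!identical(dim(f_a), dim(f_b)))
    stop("cross_modal_attention: shape mismatch")
  rec <- new.env(parent = emptyenv()); rec$ranges <- list(); rec$mult <- NULL
  # re-run recording the multiplier explicitly
  na <- bn_fwd(ad_node(f_a), weights$bn_a, training)
  nb <- bn_fwd(ad_node(f_b), weights$bn_b, training)
  mult <- NULL
  if (!is.null(weights$mask_a)) {
    ma <- ad_sigmoid(conv_fwd(ad_relu(conv_fwd(na, weights$mask_a$c1)), weights$mask_a$c2))
    mb <- ad_sigmoid(conv_fwd(ad_relu(conv_fwd(nb, weights$mask_b$c1)), weights$mask_b$c2))
    mult <- ad_shift(ad_add(ma, mb), 1)
    na <- ad_mul(na, mult)
    nb <- ad_mul(nb, mult)
  }
  out <- ad_value(conv_fwd(ad_concat_c(list(na, nb)), weights$reduce))
  attr(out, "multiplier") <- if (is.null(mult)) NULL else ad_value(mult)
  out
}

# ---- cross-branch attention (channel attention over pooled descriptors) --

cbam_init <- function(Cin, Cout, ratio, use_attention = TRUE) {
  Cr <- max(1L, Cin %/% ratio)
  w <- list(reduce = conv_init(3L, Cin, Cout), bn = bn_init(Cout))
  if (use_attention) {
    w$mlp1 <- conv_init(1L, Cin, Cr)
    w$mlp2 <- conv_init(1L, Cr, Cin)
  }
  w
}

cbam_fwd <- function(f, w, training = FALSE, rec = NULL) {
  d <- dim(ad_value(f))
  if (!is.null(w$mlp1)) {
    mlp <- function(desc) ad_sigmoid(conv_fwd(ad_relu(conv_fwd(desc, w$mlp1)), w$mlp2))
    mmax <- mlp(ad_gpool_max(f))
    mavg <- mlp(ad_gpool_avg(f))
    mult <- ad_expand(ad_shift(ad_add(mmax, mavg), 1), d[1L], d[2L])
    rec_mult(rec, mult)
    f <- ad_mul(f, mult)
  }
  bn_fwd(conv_fwd(f, w$reduce), w$bn, training)
}

#' Cross-branch attention fusion
#'
#' Channel attention over the concatenated branch features: max-pooled and
#' average-pooled channel descriptors pass through a shared two-convolution
#' bottleneck, the feature is rescaled by `1 + M_max + M_avg`, then reduced
#' by a convolution and batch-normalized.
#'
#' @param f (H, W, C) concatenated branch features.
#' @param weights a [cbam_init] weight list.
#' @param training use batch statistics in the normalization.
#' @return (H, W, Cout) array with attribute `"multiplier"`.
#' @export
cross_branch_attention <- function(f, weights, training = FALSE) {
  f <- as_hwc(f)
  if (dim(f)[3L] != dim(weights$reduce$w)[3L])
    stop("cross_branch_attention: channel mismatch")
  rec <- new.env(parent = emptyenv()); rec$ranges <- list()
  node <- cbam_fwd(ad_node(f), weights, training, rec)
  out <- ad_value(node)
  if (!is.null(weights$mlp1)) {
    # recompute the multiplier for inspection
    mlp <- function(desc) ad_value(ad_sigmoid(conv_fwd(ad_relu(conv_fwd(desc, weights$mlp1)), weights$mlp2)))
    attr(out, "multiplier") <- 1 + as.vector(mlp(ad_node(array(apply(f, 3, max), c(1, 1, dim(f)[3]))))) +
      as.vector(mlp(ad_node(array(apply(f, 3, mean), c(1, 1, dim(f)[3])))))
  }
  out
}

# ---- cross-scale attention (coordinate attention) -----------------------

csam_init <- function(Cin, Cout, ratio, use_attention = TRUE) {
  Cr <- max(1L, Cin %/% ratio)
  w <- list(reduce = conv_init(3L, Cin, Cout), bn = bn_init(Cout))
  if (use_attention) {
    w$shared <- conv_init(1L, Cin, Cr)
    w$shared_bn <- bn_init(Cr)
    w$conv_x <- conv_init(1L, Cr, Cin)
    w$conv_y <- conv_init(1L, Cr, Cin)
  }
  w
}

csam_fwd <- function(f, w, training = FALSE, rec = NULL) {
  d <- dim(ad_value(f))
  if (!is.null(w$shared)) {
    trunk <- function(strip) ad_hswish(bn_fwd(conv_fwd(strip, w$shared), w$shared_bn, training))
    mx <- ad_sigmoid(conv_fwd(trunk(ad_pool_rows(f)), w$conv_x))  # (1, W, Cin)
    my <- ad_sigmoid(conv_fwd(trunk(ad_pool_cols(f)), w$conv_y))  # (H, 1, Cin)
    mult <- ad_shift(ad_add(ad_expand(mx, d[1L], d[2L]),
                            ad_expand(my, d[1L], d[2L])), 1)
    rec_mult(rec, mult)
    f <- ad_mul(f, mult)
  }
  bn_fwd(conv_fwd(f, w$reduce), w$bn, training)
}

#' Cross-scale attention fusion
#'
#' Coordinate attention: column-wise and row-wise average pooling produce
#' directional strips, a shared bottleneck (1x1 conv, batch norm, h-swish)
#' processes each, and independent convolutions with sigmoids yield the
#' directional masks `M_x` and `M_y`. The input is rescaled by
#' `1 + M_x + M_y`, reduced by a convolution and batch-normalized.
#'
#' @param f (H, W, C) features, H and W both > 1.
#' @param weights a [csam_init] weight list.
#' @param training use batch statistics in the normalization.
#' @return (H, W, Cout) array with attribute `"multiplier"`.
#' @export
cross_scale_attention <- function(f, weights, training = FALSE) {
  f <- as_hwc(f)
  if (dim(f)[1L] < 2L || dim(f)[2L] < 2L)
    stop("cross_scale_attention: spatial size must exceed 1x1")
  rec <- new.env(parent = emptyenv()); rec$ranges <- list()
  node <- csam_fwd(ad_node(f), weights, training, rec)
  out <- ad_value(node)
  if (length(rec$ranges)) attr(out, "multiplier_range") <- rec$ranges[[1L]]
  out
}

# ---- fusion block -------------------------------------------------------

fusion_block_init <- function(C, C_prev, B, cfg) {
  use_attn <- isTRUE(cfg$fusion$use_attention)
  ratio <- cfg$fusion$attn_ratio
  blk <- list(
    cmam = lapply(seq_len(B), function(i)
      cmam_init(C, ratio, cfg$fusion$reduction_kernel, use_attn)),
    post_cmam = lapply(seq_len(B), function(i) cna_init(3L, C, C)),
    cbam = cbam_init(B * C, C, ratio, use_attn),
    post_cbam = cna_init(3L, C, C)
  )
  if (!is.null(C_prev)) {
    steps <- round(seq(C_prev, C, length.out = 4L))
    blk$prev_path <- list(cna_init(3L, C_prev, steps[2L]),
                          cna_init(3L, steps[2L], steps[3L]),
                          cna_init(3L, steps[3L], C))
    blk$csam <- csam_init(2L * C, C, ratio, use_attn)
    blk$post_csam <- cna_init(3L, C, C)
  }
  blk
}

fusion_block_fwd <- function(feats_a, feats_b, prev, blk, cfg, training = FALSE,
                             rec = NULL) {
  slope <- cfg$extract$leaky_slope
  B <- length(feats_a)
  fused <- vector("list", B)
  for (b in seq_len(B)) {
    f <- cmam_fwd(feats_a[[b]], feats_b[[b]], blk$cmam[[b]], training, rec)
    fused[[b]] <- cna_fwd(f, blk$post_cmam[[b]], training, slope)
  }
  cur <- cbam_fwd(if (B > 1L) ad_concat_c(fused) else fused[[1L]],
                  blk$cbam, training, rec)
  cur <- cna_fwd(cur, blk$post_cbam, training, slope)
  if (is.null(prev) || is.null(blk$prev_path)) return(cur)
  d <- dim(ad_value(cur))
  up <- ad_upsample_bilinear(prev, d[1L], d[2L])
  for (lay in blk$prev_path) up <- cna_fwd(up, lay, training, slope)
  out <- csam_fwd(ad_concat_c(list(cur, up)), blk$csam, training, rec)
  cna_fwd(out, blk$post_csam, training, slope)
}

#' Run one fusion/reconstruction block on plain arrays
#'
#' @param feats_a,feats_b lists of per-branch (H, W, C) arrays at the
#'   block's scale for the two modalities.
#' @param prev output of the previous (coarser) block, or NULL for the
#'   coarsest block, which performs no cross-scale processing.
#' @param weights a [fusion_block_init] weight list.
#' @param config a `semfuse_config`.
#' @param training use batch statistics in normalization layers.
#' @return (H, W, C) fused feature array.
#' @export
fusion_block_forward <- function(feats_a, feats_b, prev, weights, config,
                                 training = FALSE) {
  if (length(feats_a) != length(weights$cmam))
    stop_config("fusion_block_forward: expected %d branch features",
                length(weights$cmam))
  node <- fusion_block_fwd(lapply(feats_a, function(f) ad_node(as_hwc(f))),
                           lapply(feats_b, function(f) ad_node(as_hwc(f))),
                           if (is.null(prev)) NULL else ad_node(as_hwc(prev)),
                           weights, config, training)
  ad_value(node)
}

# ---- reconstruction head ------------------------------------------------

recon_init <- function(C, cfg) {
  rc <- as.integer(cfg$fusion$recon_channels)
  list(l1 = cna_init(3L, C, rc[1L]),
       l2 = cna_init(3L, rc[1L], rc[2L]),
       l3 = conv_init(3L, rc[2L], 1L))
}

recon_fwd <- function(x, w, cfg, training = FALSE) {
  slope <- cfg$extract$leaky_slope
  x <- cna_fwd(x, w$l1, training, slope)
  x <- cna_fwd(x, w$l2, training, slope)
  ad_sigmoid(conv_fwd(x, w$l3))
}

#' Reconstruct a fused image from full-resolution fused features
#'
#' Three 3x3 convolutional layers (batch norm + LeakyReLU on the first
#' two) followed by a sigmoid, guaranteeing output in \[0,1\].
#'
#' @param final_features (H, W, C) fused features at image resolution.
#' @param weights a [recon_init] weight list.
#' @param config a `semfuse_config`.
#' @param training use batch statistics.
#' @return H x W matrix in \[0,1\].
#' @export
reconstruct <- function(final_features, weights, config, training = FALSE) {
  v <- ad_value(recon_fwd(ad_node(as_hwc(final_features)), weights, config, training))
  v[, , 1L]
}

# ---- whole fusion network ----------------------------------------------

fusion_net_init <- function(cfg) {
  ch <- as.integer(cfg$extract$channels)
  S <- length(ch)
  B <- cfg$extract$branches
  blocks <- vector("list", S)
  for (s in seq_len(S)) {
    C_prev <- if (s < S) ch[s + 1L] else NULL
    blocks[[s]] <- fusion_block_init(ch[s], C_prev, B, cfg)
  }
  list(ext = extractor_init(cfg), blocks = blocks, recon = recon_init(ch[1L], cfg))
}

fuse_fwd <- function(xa, xb, net, cfg, training = FALSE, rec = NULL) {
  slope <- cfg$extract$leaky_slope
  feats <- extract_fwd(xa, xb, net$ext, slope)
  S <- length(net$blocks)
  prev <- NULL
  for (s in rev(seq_len(S))) {
    fa <- lapply(feats$a, `[[`, s)
    fb <- lapply(feats$b, `[[`, s)
    prev <- fusion_block_fwd(fa, fb, prev, net$blocks[[s]], cfg, training, rec)
  }
  recon_fwd(prev, net$recon, cfg, training)
}

#' Fuse a registered image pair
#'
#' Full forward pass: feature extraction, five attention fusion blocks
#' coarse-to-fine, reconstruction head. Deterministic given the model
#' state (normalization layers use running statistics).
#'
#' @param pair a `registered_pair` or list with `image_a`, `image_b`.
#' @param model a model from [init_model()] or [semfuse()].
#' @return H x W fused image in \[0,1\].
#' @export
fuse_images <- function(pair, model) {
  if (!identical(dim(pair$image_a), dim(pair$image_b)))
    stop("fuse_images: images must be registered (equal size)")
  v <- ad_value(fuse_fwd(ad_node(as_hwc(pair$image_a)),
                         ad_node(as_hwc(pair$image_b)),
                         model$fusion, model$config, training = FALSE))
  v[, , 1L]
}
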