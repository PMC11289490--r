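# Parameter-tree plumbing and optimizer.
#
# A network's weights are a nested list whose numeric leaves are arrays
# (conv kernels, biases, BN scale/shift) and whose environment leaves are
# BN running statistics. The helpers below walk that tree: wrapping leaves
# as autodiff nodes for a training step, harvesting gradients, and
# flattening to a named list for the optimizer and for checkpoints.

map_num_leaves <- function(x, f) {
  if (is.list(x)) lapply(x, map_num_leaves, f = f)
  else if (is.numeric(x)) f(x)
  else x
}

# wrap numeric leaves as trainable nodes (environments pass through)
wrap_params <- function(theta) map_num_leaves(theta, ad_leaf)

# pull gradients out of a wrapped tree, preserving structure
grads_of <- function(wrapped) {
  if (inherits(wrapped, "ad_node")) ad_grad(wrapped)
  else if (is.list(wrapped)) lapply(wrapped, grads_of)
  else wrapped
}

# flat named list of the numeric leaves, in stable traversal order
flatten_num <- function(x, prefix = "") {
  out <- list()
  if (is.list(x)) {
    nms <- names(x)
    if (is.null(nms)) nms <- as.character(seq_along(x))
    for (i in seq_along(x)) {
      out <- c(out, flatten_num(x[[i]], paste0(prefix, ".", nms[i])))
    }
  } else if (is.numeric(x)) {
    out[[substring(prefix, 2L)]] <- x
  }
  out
}

# write a flat list of numeric leaves back into the tree (same order)
unflatten_num <- function(x, flat, counter = NULL) {
  if (is.null(counter)) {
    counter <- new.env(parent = emptyenv())
    counter$i <- 0L
  }
  if (is.list(x)) {
    for (i in seq_along(x)) x[[i]] <- unflatten_num(x[[i]], flat, counter)
    x
  } else if (is.numeric(x)) {
    counter$i <- counter$i + 1L
    v <- flat[[counter$i]]
    if (!is.null(dim(x))) dim(v) <- dim(x)
    v
  } else x
}

# BN statistics environments <-> plain lists, for serializable checkpoints
stats_to_list <- function(x) {
  if (is.environment(x)) list(.bnstats = TRUE, rm = x$rm, rv = x$rv)
  else if (is.list(x)) lapply(x, stats_to_list)
  else x
}

stats_from_list <- function(x) {
  if (is.list(x) && isTRUE(x$.bnstats)) {
    e <- new.env(parent = emptyenv())
    e$rm <- x$rm
    e$rv <- x$rv
    e
  } else if (is.list(x)) lapply(x, stats_from_list)
  else x
}

# ---- layer constructors -------------------------------------------------

conv_init <- function(k, cin, cout, gain = 2) {
  list(w = array(stats::rnorm(k * k * cin * cout, sd = sqrt(gain / (k * k * cin))),
                 c(k, k, cin, cout)),
       b = numeric(cout))
}

bn_init <- function(c) {
  list(gamma = rep(1, c), beta = numeric(c), stats = bn_stats_new(c))
}

conv_fwd <- function(x, lay, stride = 1L) ad_conv2d(x, lay$w, lay$b, stride = stride)

bn_fwd <- function(x, lay, training) {
  ad_bn(x, lay$gamma, lay$beta, stats = lay$stats, training = training)
}

# conv + batch norm + LeakyReLU, the ubiquitous "conv-norm-activation"
cna_init <- function(k, cin, cout) list(conv = conv_init(k, cin, cout), bn = bn_init(cout))

cna_fwd <- function(x, lay, training, slope = 0.01, stride = 1L) {
  ad_leaky_relu(bn_fwd(conv_fwd(x, lay$conv, stride), lay$bn, training), slope)
}

# ---- Adam ---------------------------------------------------------------

adam_new <- function(lr = 1e-4, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
       m = NULL, v = NULL)
}

adam_step <- function(opt, flat_w, flat_g) {
  if (is.null(opt$m)) {
    opt$m <- lapply(flat_w, function(x) x * 0)
    opt$v <- lapply(flat_w, function(x) x * 0)
  }
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (i in seq_along(flat_w)) {
    g <- flat_g[[i]]
    opt$m[[i]] <- opt$beta1 * opt$m[[i]] + (1 - opt$beta1) * g
    opt$v[[i]] <- opt$beta2 * opt$v[[i]] + (1 - opt$beta2) * g^2
    flat_w[[i]] <- flat_w[[i]] -
      opt$lr * (opt$m[[i]] / bc1) / (sqrt(opt$v[[i]] / bc2) + opt$eps)
  }
  list(opt = opt, w = flat_w)
}
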