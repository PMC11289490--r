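# Shared fixtures: desk-scale configurations and seeded random inputs.

tiny_cfg <- function(...) {
  base <- list(
    extract = list(channels = c(4L, 6L, 8L, 10L, 12L)),
    semantic = list(K = 4L, width = 6L, feature_dim = 8L),
    training = list(fusion_epochs = 1L, seg_epochs = 1L, cycles = 1L,
                    batch_size = 2L, seed = 0L))
  over <- list(...)
  for (nm in names(over)) {
    base[[nm]] <- utils::modifyList(if (is.null(base[[nm]])) list() else base[[nm]],
                                    over[[nm]])
  }
  do.call(fusion_config, base)
}

rand_img <- function(h, w = h, seed = 1) {
  withr::with_seed(seed, matrix(runif(h * w), h, w))
}

rand_feat <- function(h, w, c, seed = 1, sd = 0.5) {
  withr::with_seed(seed, array(rnorm(h * w * c, sd = sd), c(h, w, c)))
}

small_pair <- function(seed = 5, size = 64L) {
  generate_pair(phantom_spec(height = size, width = size, n_foci_a = 2L,
                             n_masses_b = 1L, seed = seed))
}

# zero out every numeric leaf of a weight tree
zero_weights <- function(theta) semfuse:::map_num_leaves(theta, function(x) x * 0)

fd_gradient <- function(fn, x, eps = 1e-5) {
  g <- array(0, dim(x))
  for (i in seq_along(x)) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + eps
    xm[i] <- xm[i] - eps
    g[i] <- (fn(xp) - fn(xm)) / (2 * eps)
  }
  g
}
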