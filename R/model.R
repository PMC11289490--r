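# User-facing model interface: one fitting function returning a classed
# object with print / summary / predict / plot methods.

#' Fit a semantic-aware fusion model
#'
#' Trains the multi-branch multi-scale fusion network and the unsupervised
#' segmentation network in alternation on a set of registered image pairs
#' (see [alternating_train()] for the schedule). The returned object fuses
#' new pairs via [predict()].
#'
#' @param data list of `registered_pair`s, or the output of
#'   [generate_dataset()].
#' @param config a [fusion_config()].
#' @param out_dir optional directory for checkpoints and the training log.
#' @return object of class `semfuse_model`.
#' @export
#' @examples
#' \donttest{
#' cfg <- fusion_config(
#'   extract = list(channels = c(6L, 8L, 12L, 16L, 16L)),
#'   training = list(fusion_epochs = 1L, seg_epochs = 1L, cycles = 1L,
#'                   batch_size = 2L))
#' ds <- generate_dataset(2, phantom_spec(height = 64L, width = 64L))
#' fit <- semfuse(ds, cfg)
#' fused <- predict(fit, ds$pairs[[1]])
#' }
semfuse <- function(data, config = fusion_config(), out_dir = NULL) {
  model <- alternating_train(config, data, out_dir = out_dir)
  model$call <- match.call()
  class(model) <- "semfuse_model"
  model
}

n_params <- function(theta) sum(vapply(flatten_num(theta), length, numeric(1)))

#' @export
print.semfuse_model <- function(x, ...) {
  cfg <- x$config
  cat("semfuse fusion model\n")
  cat(sprintf("  scales: %d  branches: %d  channels: %s\n",
              n_scales(cfg), cfg$extract$branches,
              paste(cfg$extract$channels, collapse = "/")))
  cat(sprintf("  fusion net parameters: %d   segmentation net parameters: %d\n",
              n_params(x$fusion), n_params(x$seg)))
  cat(sprintf("  attention: %s   semantic loss: %s (K = %d)\n",
              if (cfg$fusion$use_attention) "on" else "off",
              if (cfg$loss$use_semantic) "on" else "off", cfg$semantic$K))
  if (nrow(x$history)) {
    last <- utils::tail(x$history[x$history$phase == "fusion", ], 1L)
    cat(sprintf("  trained %d steps; last fusion loss %.4f\n",
                nrow(x$history), last$L))
  } else cat("  untrained\n")
  invisible(x)
}

#' @export
summary.semfuse_model <- function(object, ...) {
  h <- object$history
  out <- list(config = object$config, steps = nrow(h))
  if (nrow(h)) {
    agg <- stats::aggregate(h$L, by = list(phase = h$phase, cycle = h$cycle),
                            FUN = mean)
    names(agg)[3L] <- "mean_loss"
    out$phase_loss <- agg
  }
  class(out) <- "summary.semfuse_model"
  out
}

#' @export
print.summary.semfuse_model <- function(x, ...) {
  cat(sprintf("semfuse model, %d training steps\n", x$steps))
  if (!is.null(x$phase_loss)) {
    cat("mean loss by phase and cycle:\n")
    print(x$phase_loss, row.names = FALSE)
  }
  invisible(x)
}

#' Fuse image pairs with a fitted model
#'
#' @param object a `semfuse_model`.
#' @param pair a `registered_pair`, a list of pairs, or NULL if `image_a`
#'   and `image_b` are given.
#' @param image_a,image_b registered matrices in \[0,1\].
#' @param ... unused.
#' @return fused H x W matrix, or a list of them for a list input.
#' @export
predict.semfuse_model <- function(object, pair = NULL, image_a = NULL,
                                  image_b = NULL, ...) {
  if (is.null(pair)) {
    stopifnot(!is.null(image_a), !is.null(image_b))
    pair <- list(image_a = image_a, image_b = image_b)
  }
  pairs <- as_pair_list(pair)
  if (inherits(pair, "registered_pair") ||
      (!is.null(pair$image_a) && is.matrix(pair$image_a)))
    return(fuse_images(pair, object))
  lapply(pairs, fuse_images, model = object)
}

#' Display a source pair and its fusion
#'
#' @param x a `semfuse_model`.
#' @param pair a `registered_pair`.
#' @param ... passed to [graphics::image()].
#' @export
plot.semfuse_model <- function(x, pair, ...) {
  fused <- fuse_images(pair, x)
  old <- graphics::par(mfrow = c(1, 3), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(old))
  show <- function(m, main) graphics::image(t(m)[, nrow(m):1],
                                            col = grDevices::gray.colors(256, 0, 1),
                                            axes = FALSE, main = main, ...)
  show(pair$image_a, "modality A")
  show(pair$image_b, "modality B")
  show(fused, "fused")
  invisible(fused)
}
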