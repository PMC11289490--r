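# Run configuration: nested sections with defaults, strict key checking,
# and YAML round-tripping.

default_config <- function() {
  list(
    extract = list(
      channels = c(16L, 32L, 64L, 128L, 256L),  # widths per scale
      leaky_slope = 0.01,
      branches = 3L,
      share_modality = FALSE
    ),
    fusion = list(
      upsample = "bilinear",
      reduction_kernel = 1L,
      attn_ratio = 4L,
      use_attention = TRUE,
      recon_channels = c(16L, 8L)
    ),
    loss = list(
      alpha = 5,
      ssim_window = 11L,
      ssim_sigma = 1.5,
      use_semantic = TRUE
    ),
    semantic = list(
      K = 8L,
      feature_dim = 32L,
      width = 16L,
      kmeans_iters = 10L,
      jitter = list(brightness = 0.08, contrast = 0.1, gamma = 0.1),
      geo = "hflip"
    ),
    training = list(
      fusion_epochs = 20L,
      seg_epochs = 10L,
      cycles = 5L,
      batch_size = 4L,
      lr = 1e-3,
      seed = 0L
    ),
    metrics = list(aggregate = "mean")
  )
}

merge_config <- function(base, user, path = "") {
  for (k in names(user)) {
    if (!k %in% names(base))
      stop_config("unknown config key: %s%s", path, k)
    if (is.list(base[[k]]) && is.list(user[[k]])) {
      base[[k]] <- merge_config(base[[k]], user[[k]], paste0(path, k, "."))
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

#' Build a run configuration
#'
#' Starts from package defaults and overlays the named sections given;
#' unknown keys are rejected. See the methods vignette for the meaning and
#' units of every field.
#'
#' @param ... named sections (`extract`, `fusion`, `loss`, `semantic`,
#'   `training`, `metrics`), each a list of overrides.
#' @return nested list of class `semfuse_config`.
#' @export
#' @examples
#' cfg <- fusion_config(loss = list(alpha = 5), semantic = list(K = 4))
fusion_config <- function(...) {
  user <- list(...)
  cfg <- merge_config(default_config(), user)
  validate_config(cfg)
  structure(cfg, class = "semfuse_config")
}

validate_config <- function(cfg) {
  ch <- cfg$extract$channels
  if (!is.numeric(ch) || length(ch) < 1L || any(ch < 1))
    stop_config("extract.channels must be a positive integer vector")
  if (!cfg$extract$branches %in% c(1L, 3L))
    stop_config("extract.branches must be 1 or 3")
  if (cfg$loss$alpha < 0) stop_config("loss.alpha must be >= 0")
  if (cfg$semantic$K < 1) stop_config("semantic.K must be >= 1")
  jit <- cfg$semantic$jitter
  if (any(unlist(jit) < 0) || jit$contrast >= 1 || jit$gamma >= 1)
    stop_config("semantic.jitter bounds must be in [0, 1)")
  tr <- cfg$training
  if (any(c(tr$fusion_epochs, tr$seg_epochs, tr$cycles, tr$batch_size) < 1))
    stop_config("training counts must be >= 1")
  if (tr$lr <= 0) stop_config("training.lr must be > 0")
  if (!cfg$metrics$aggregate %in% c("mean", "max"))
    stop_config("metrics.aggregate must be 'mean' or 'max'")
  invisible(cfg)
}

#' Read / write a configuration as YAML
#' @param path file path.
#' @rdname config_io
#' @export
config_read <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: %s", path)
  user <- yaml::read_yaml(path)
  cfg <- merge_config(default_config(), user)
  validate_config(cfg)
  structure(cfg, class = "semfuse_config")
}

#' @param cfg a `semfuse_config`.
#' @rdname config_io
#' @export
config_write <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

n_scales <- function(cfg) length(cfg$extract$channels)
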