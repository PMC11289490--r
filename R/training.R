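# Alternating training of the fusion and segmentation networks.
#
# Within a phase only one network's parameters are updated: the fusion
# phase minimizes content + similarity + semantic loss with the
# segmentation weights frozen (gradients still flow through the frozen
# encoder into the fused image); the segmentation phase fuses with the
# frozen fusion network and minimizes the semantic loss alone. A cycle is
# one fusion phase followed by one segmentation phase.

#' Initialize an untrained model
#'
#' @param config a `semfuse_config`.
#' @param seed integer seed for weight initialization (defaults to
#'   `config$training$seed`).
#' @return model list with `fusion` and `seg` weight trees, Adam states,
#'   and an empty loss history.
#' @export
init_model <- function(config = fusion_config(), seed = NULL) {
  validate_config(config)
  if (is.null(seed)) seed <- config$training$seed
  with_seed(seed, {
    fusion <- fusion_net_init(config)
    seg <- seg_init(config)
    list(config = config, fusion = fusion, seg = seg,
         opt_f = adam_new(lr = config$training$lr),
         opt_s = adam_new(lr = config$training$lr),
         history = empty_history(), seed = as.integer(seed), ctr = 0L)
  })
}

empty_history <- function() {
  data.frame(step = integer(0), phase = character(0), cycle = integer(0),
             epoch = integer(0), L = numeric(0), L_int = numeric(0),
             L_texture = numeric(0), L_similarity = numeric(0),
             L_semantic = numeric(0), stringsAsFactors = FALSE)
}

# deterministic per-event seed stream below 2^31
next_seed <- function(model) {
  (model$seed * 131L + model$ctr * 7919L) %% 2147483647L
}

as_pair_list <- function(dataset) {
  if (inherits(dataset, "registered_pair")) return(list(dataset))
  if (is.list(dataset) && !is.null(dataset$pairs)) return(dataset$pairs)
  dataset
}

# one optimization step of the fusion network over a batch of pairs
fusion_step <- function(model, batch, seed) {
  cfg <- model$config
  wrapped <- wrap_params(model$fusion)
  tot <- NULL
  comps <- c(L_int = 0, L_texture = 0, L_similarity = 0, L_semantic = 0)
  fused_nodes <- vector("list", length(batch))
  per_pair <- vector("list", length(batch))
  for (i in seq_along(batch)) {
    p <- batch[[i]]
    fused <- fuse_fwd(ad_node(as_hwc(p$image_a)), ad_node(as_hwc(p$image_b)),
                      wrapped, cfg, training = TRUE)
    fused_nodes[[i]] <- fused
    tmax <- pmax(p$image_a, p$image_b)
    gmax <- pmax(sobel_gradient(p$image_a), sobel_gradient(p$image_b))
    li <- intensity_loss_node(fused, as_hwc(tmax))
    lt <- texture_loss_node(fused, as_hwc(gmax))
    ls <- similarity_loss_node(fused, ad_node(as_hwc(p$image_a)),
                               ad_node(as_hwc(p$image_b)),
                               cfg$loss$ssim_window, cfg$loss$ssim_sigma)
    per_pair[[i]] <- list(li = li, lt = lt, ls = ls)
  }
  if (isTRUE(cfg$loss$use_semantic) && cfg$semantic$K > 1L) {
    sem <- semantic_loss_node(fused_nodes, model$seg, cfg, seed,
                              slope = cfg$extract$leaky_slope)
    sem_node <- sem$total
  } else {
    sem_node <- ad_node(0)
  }
  nb <- length(batch)
  for (i in seq_len(nb)) {
    contrib <- ad_add(ad_add(per_pair[[i]]$li,
                             ad_scale(per_pair[[i]]$lt, cfg$loss$alpha)),
                      per_pair[[i]]$ls)
    tot <- if (is.null(tot)) contrib else ad_add(tot, contrib)
    comps["L_int"] <- comps["L_int"] + ad_value(per_pair[[i]]$li) / nb
    comps["L_texture"] <- comps["L_texture"] + ad_value(per_pair[[i]]$lt) / nb
    comps["L_similarity"] <- comps["L_similarity"] + ad_value(per_pair[[i]]$ls) / nb
  }
  tot <- ad_add(ad_scale(tot, 1 / nb), sem_node)
  comps["L_semantic"] <- ad_value(sem_node)
  ad_backward(tot)
  flat_w <- flatten_num(model$fusion)
  flat_g <- flatten_num(grads_of(wrapped))
  upd <- adam_step(model$opt_f, flat_w, flat_g)
  model$opt_f <- upd$opt
  model$fusion <- unflatten_num(model$fusion, upd$w)
  list(model = model, L = ad_value(tot), comps = comps)
}

# one optimization step of the segmentation network
seg_step <- function(model, batch, seed) {
  cfg <- model$config
  fused <- lapply(batch, function(p) ad_node(as_hwc(fuse_images(p, model))))
  wrapped <- wrap_params(model$seg)
  sem <- semantic_loss_node(fused, wrapped, cfg, seed,
                            slope = cfg$extract$leaky_slope)
  ad_backward(sem$total)
  flat_w <- flatten_num(model$seg)
  flat_g <- flatten_num(grads_of(wrapped))
  upd <- adam_step(model$opt_s, flat_w, flat_g)
  model$opt_s <- upd$opt
  model$seg <- unflatten_num(model$seg, upd$w)
  list(model = model, L = ad_value(sem$total), comps = c(
    L_int = NA, L_texture = NA, L_similarity = NA,
    L_semantic = ad_value(sem$total)))
}

run_phase <- function(model, pairs, epochs, phase, cycle, log_path = NULL) {
  cfg <- model$config
  bs <- cfg$training$batch_size
  n <- length(pairs)
  for (ep in seq_len(epochs)) {
    model$ctr <- model$ctr + 1L
    ord <- with_seed(next_seed(model), sample.int(n))
    starts <- seq.int(1L, n, by = bs)
    for (s in starts) {
      batch <- pairs[ord[s:min(s + bs - 1L, n)]]
      model$ctr <- model$ctr + 1L
      step_seed <- next_seed(model)
      res <- if (phase == "fusion") fusion_step(model, batch, step_seed)
             else seg_step(model, batch, step_seed)
      model <- res$model
      row <- data.frame(step = nrow(model$history) + 1L, phase = phase,
                        cycle = cycle, epoch = ep, L = res$L,
                        L_int = unname(res$comps["L_int"]),
                        L_texture = unname(res$comps["L_texture"]),
                        L_similarity = unname(res$comps["L_similarity"]),
                        L_semantic = unname(res$comps["L_semantic"]),
                        stringsAsFactors = FALSE)
      model$history <- rbind(model$history, row)
      if (!is.null(log_path))
        cat(jsonlite::toJSON(as.list(row), auto_unbox = TRUE), "\n",
            file = log_path, append = TRUE)
    }
  }
  model
}

#' Train the fusion network for a number of epochs (segmentation frozen)
#'
#' @param model model from [init_model()] or a previous phase.
#' @param dataset list of `registered_pair`s (or [generate_dataset()] output).
#' @param epochs epochs to run.
#' @param cycle cycle index recorded in the history.
#' @param log_path optional JSON-lines log file, appended per step.
#' @return updated model.
#' @export
train_fusion_phase <- function(model, dataset, epochs, cycle = 1L,
                               log_path = NULL) {
  pairs <- as_pair_list(dataset)
  if (!length(pairs)) stop_config("dataset must be non-empty")
  run_phase(model, pairs, epochs, "fusion", cycle, log_path)
}

#' Train the segmentation network for a number of epochs (fusion frozen)
#'
#' @inheritParams train_fusion_phase
#' @return updated model.
#' @export
train_seg_phase <- function(model, dataset, epochs, cycle = 1L,
                            log_path = NULL) {
  pairs <- as_pair_list(dataset)
  if (!length(pairs)) stop_config("dataset must be non-empty")
  if (!isTRUE(model$config$loss$use_semantic))
    return(model)  # semantic term disabled: nothing to train
  run_phase(model, pairs, epochs, "seg", cycle, log_path)
}

#' Alternating training protocol
#'
#' Runs `cycles` cycles of (`fusion_epochs` fusion epochs, then
#' `seg_epochs` segmentation epochs) with the configured defaults of 5
#' cycles of (20, 10). Fully seeded: weight initialization, data order,
#' photometric transforms and k-means all derive from
#' `config$training$seed`.
#'
#' @param config a `semfuse_config`.
#' @param dataset list of `registered_pair`s or [generate_dataset()] output.
#' @param out_dir optional directory for per-phase checkpoints and the
#'   JSON-lines training log.
#' @return trained model list.
#' @export
alternating_train <- function(config, dataset, out_dir = NULL) {
  validate_config(config)
  pairs <- as_pair_list(dataset)
  if (!length(pairs)) stop_config("dataset must be non-empty")
  model <- init_model(config)
  log_path <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    log_path <- file.path(out_dir, "train_log.jsonl")
  }
  for (cy in seq_len(config$training$cycles)) {
    model <- train_fusion_phase(model, pairs, config$training$fusion_epochs,
                                cycle = cy, log_path = log_path)
    if (!is.null(out_dir))
      checkpoint_save(model, file.path(out_dir, sprintf("cycle%02d_fusion.rds", cy)))
    model <- train_seg_phase(model, pairs, config$training$seg_epochs,
                             cycle = cy, log_path = log_path)
    if (!is.null(out_dir))
      checkpoint_save(model, file.path(out_dir, sprintf("cycle%02d_seg.rds", cy)))
  }
  model
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single serialized state file plus a JSON sidecar
#' echoing the configuration and counters; save -> load -> save is
#' byte-identical.
#'
#' @param model model list.
#' @param path checkpoint path (`.rds`); the sidecar is `path` + `.json`.
#' @rdname checkpoint
#' @export
checkpoint_save <- function(model, path) {
  snap <- model
  snap$fusion <- stats_to_list(model$fusion)
  snap$seg <- stats_to_list(model$seg)
  snap$config <- unclass(model$config)
  saveRDS(snap, path, version = 2L)
  sidecar <- list(package = "semfuse",
                  version = as.character(utils::packageVersion("semfuse")),
                  seed = model$seed, steps = nrow(model$history),
                  config = unclass(model$config))
  writeLines(jsonlite::toJSON(sidecar, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA),
             paste0(path, ".json"))
  invisible(path)
}

#' @rdname checkpoint
#' @export
checkpoint_load <- function(path) {
  snap <- readRDS(path)
  snap$fusion <- stats_from_list(snap$fusion)
  snap$seg <- stats_from_list(snap$seg)
  snap$config <- structure(snap$config, class = "semfuse_config")
  snap
}
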