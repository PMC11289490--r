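# training-phase contracts at desk scale (32x32 phantoms, narrow nets)

train_fixture <- function(n = 2L, size = 32L, seed = 40L) {
  generate_dataset(n, phantom_spec(height = size, width = size,
                                   n_foci_a = 1L, n_masses_b = 1L,
                                   seed = seed))$pairs
}

test_that("the fusion phase freezes the segmentation network and logs every step", {
  cfg <- tiny_cfg()
  model <- init_model(cfg, seed = 1)
  pairs <- train_fixture()
  seg_before <- semfuse:::param_fingerprint(semfuse:::flatten_num(model$seg))
  fus_before <- semfuse:::param_fingerprint(semfuse:::flatten_num(model$fusion))
  m2 <- train_fusion_phase(model, pairs, epochs = 2L)
  expect_identical(semfuse:::param_fingerprint(semfuse:::flatten_num(m2$seg)),
                   seg_before)
  expect_false(identical(
    semfuse:::param_fingerprint(semfuse:::flatten_num(m2$fusion)), fus_before))
  # 2 pairs, batch 2 -> 1 step per epoch
  expect_identical(nrow(m2$history), 2L)
  expect_true(all(m2$history$phase == "fusion"))
  expect_error(train_fusion_phase(model, list(), 1L), "non-empty")
})

test_that("the segmentation phase freezes the fusion network", {
  cfg <- tiny_cfg()
  model <- init_model(cfg, seed = 2)
  pairs <- train_fixture(seed = 41L)
  fus_before <- semfuse:::param_fingerprint(semfuse:::flatten_num(model$fusion))
  seg_before <- semfuse:::param_fingerprint(semfuse:::flatten_num(model$seg))
  m2 <- train_seg_phase(model, pairs, epochs = 1L)
  expect_identical(semfuse:::param_fingerprint(semfuse:::flatten_num(m2$fusion)),
                   fus_before)
  expect_false(identical(
    semfuse:::param_fingerprint(semfuse:::flatten_num(m2$seg)), seg_before))
  expect_true(all(m2$history$phase == "seg"))
})

test_that("alternating training follows the configured cycle schedule", {
  cfg <- tiny_cfg(training = list(fusion_epochs = 2L, seg_epochs = 1L,
                                  cycles = 2L, batch_size = 2L))
  pairs <- train_fixture(seed = 42L)
  model <- alternating_train(cfg, pairs)
  h <- model$history
  # per cycle: 2 fusion epochs x 1 step, then 1 seg epoch x 1 step
  expect_identical(h$phase,
                   rep(c("fusion", "fusion", "seg"), times = 2L))
  expect_identical(h$cycle, rep(1:2, each = 3L))
  # the defaults encode the published schedule
  dflt <- fusion_config()
  expect_identical(dflt$training$fusion_epochs, 20L)
  expect_identical(dflt$training$seg_epochs, 10L)
  expect_identical(dflt$training$cycles, 5L)
})

test_that("training is reproducible under a fixed seed", {
  cfg <- tiny_cfg()
  pairs <- train_fixture(seed = 43L)
  m1 <- alternating_train(cfg, pairs)
  m2 <- alternating_train(cfg, pairs)
  expect_equal(m1$history, m2$history, tolerance = 1e-14)
  expect_identical(semfuse:::param_fingerprint(semfuse:::flatten_num(m1$fusion)),
                   semfuse:::param_fingerprint(semfuse:::flatten_num(m2$fusion)))
})

test_that("checkpoints round-trip byte-identically and resume cleanly", {
  dir <- withr::local_tempdir()
  cfg <- tiny_cfg()
  model <- init_model(cfg, seed = 3)
  pairs <- train_fixture(seed = 44L)
  model <- train_fusion_phase(model, pairs, epochs = 1L)
  p1 <- file.path(dir, "ck1.rds")
  p2 <- file.path(dir, "ck2.rds")
  checkpoint_save(model, p1)
  loaded <- checkpoint_load(p1)
  checkpoint_save(loaded, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  expect_identical(readLines(paste0(p1, ".json")), readLines(paste0(p2, ".json")))
  # resuming continues the schedule without disturbing frozen weights
  fus <- semfuse:::param_fingerprint(semfuse:::flatten_num(loaded$fusion))
  resumed <- train_seg_phase(loaded, pairs, epochs = 1L)
  expect_identical(semfuse:::param_fingerprint(semfuse:::flatten_num(resumed$fusion)),
                   fus)
  expect_identical(utils::tail(resumed$history$phase, 1L), "seg")
})

test_that("the training log is written as JSON lines", {
  dir <- withr::local_tempdir()
  cfg <- tiny_cfg()
  pairs <- train_fixture(seed = 45L)
  alternating_train(cfg, pairs, out_dir = dir)
  log <- readLines(file.path(dir, "train_log.jsonl"))
  log <- log[nzchar(trimws(log))]
  expect_identical(length(log), 2L)  # 1 fusion + 1 seg step
  rec <- jsonlite::fromJSON(log[1])
  expect_true(all(c("step", "phase", "L", "L_semantic") %in% names(rec)))
  expect_true(file.exists(file.path(dir, "cycle01_fusion.rds")))
  expect_true(file.exists(file.path(dir, "cycle01_seg.rds")))
})

test_that("the fitted-model interface predicts, prints and summarizes", {
  cfg <- tiny_cfg()
  pairs <- train_fixture(seed = 46L)
  fit <- semfuse(pairs, cfg)
  expect_s3_class(fit, "semfuse_model")
  fused <- predict(fit, pairs[[1]])
  expect_identical(dim(fused), dim(pairs[[1]]$image_a))
  both <- predict(fit, pairs)
  expect_length(both, 2L)
  expect_output(print(fit), "semfuse fusion model")
  expect_output(print(summary(fit)), "training steps")
  f2 <- predict(fit, image_a = pairs[[1]]$image_a, image_b = pairs[[1]]$image_b)
  expect_identical(f2, fused)
})

test_that("ablation variants train and fuse", {
  pairs <- train_fixture(seed = 47L)
  variants <- list(
    no_semantic = tiny_cfg(loss = list(use_semantic = FALSE)),
    no_attention = tiny_cfg(fusion = list(use_attention = FALSE)),
    single_branch = tiny_cfg(extract = list(branches = 1L)),
    single_scale = tiny_cfg(extract = list(channels = 6L))
  )
  for (nm in names(variants)) {
    model <- alternating_train(variants[[nm]], pairs)
    fused <- fuse_images(pairs[[1]], model)
    expect_identical(dim(fused), dim(pairs[[1]]$image_a))
    expect_true(all(fused >= 0 & fused <= 1))
  }
  # with the semantic term disabled no segmentation steps are recorded and
  # the semantic component is zero throughout
  m <- alternating_train(variants$no_semantic, pairs)
  expect_false(any(m$history$phase == "seg"))
  expect_true(all(m$history$L_semantic == 0))
  # single-scale models instantiate exactly one fusion block
  m1 <- init_model(variants$single_scale)
  expect_length(m1$fusion$blocks, 1L)
})
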