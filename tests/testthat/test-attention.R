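test_that("zero attention weights give flat masks of one half", {
  w <- withr::with_seed(1, semfuse:::cmam_init(2L, 4L))
  w$mask_a <- zero_weights(w$mask_a)
  w$mask_b <- zero_weights(w$mask_b)
  out <- cross_modal_attention(rand_feat(4, 4, 2, seed = 1),
                               rand_feat(4, 4, 2, seed = 2), w)
  # sigmoid(0) = 0.5 from both masks: multiplier exactly 2 everywhere
  expect_equal(attr(out, "multiplier"), array(2, c(4, 4, 2)))
})

test_that("cross-modal attention equals its scalar loop oracle", {
  for (seed in 1:3) {
    w <- withr::with_seed(seed, semfuse:::cmam_init(1L + seed %% 2L, 2L))
    C <- dim(w$reduce$w)[4]
    fa <- rand_feat(4, 4, C, seed = 10 + seed)
    fb <- rand_feat(4, 4, C, seed = 20 + seed)
    got <- cross_modal_attention(fa, fb, w)
    ref <- oracle_cmam(fa, fb, w)
    expect_equal(as.vector(got), as.vector(ref$value), tolerance = 1e-5)
    expect_equal(as.vector(attr(got, "multiplier")), as.vector(ref$mult),
                 tolerance = 1e-5)
    expect_true(all(attr(got, "multiplier") > 1 & attr(got, "multiplier") < 3))
  }
})

test_that("cross-branch attention equals its scalar loop oracle and collapses pooled masks on constants", {
  w <- withr::with_seed(4, semfuse:::cbam_init(2L, 2L, 2L))
  f <- rand_feat(4, 4, 2, seed = 31)
  got <- cross_branch_attention(f, w)
  ref <- oracle_cbam(f, w)
  expect_equal(as.vector(got), as.vector(ref$value), tolerance = 1e-5)
  # constant input: max-pool and avg-pool descriptors coincide
  cst <- array(0.6, c(4, 4, 2))
  refc <- oracle_cbam(cst, w)
  expect_equal(refc$mmax, refc$mavg, tolerance = 1e-12)
  expect_error(cross_branch_attention(rand_feat(4, 4, 3), w), "channel")
})

test_that("cross-scale attention equals its scalar loop oracle", {
  w <- withr::with_seed(5, semfuse:::csam_init(1L, 1L, 1L))
  f <- rand_feat(4, 4, 1, seed = 41)
  expect_equal(as.vector(cross_scale_attention(f, w)),
               as.vector(oracle_csam(f, w)), tolerance = 1e-5)
  w2 <- withr::with_seed(6, semfuse:::csam_init(3L, 2L, 2L))
  f2 <- rand_feat(5, 6, 3, seed = 42)
  expect_equal(as.vector(cross_scale_attention(f2, w2)),
               as.vector(oracle_csam(f2, w2)), tolerance = 1e-5)
  expect_error(cross_scale_attention(array(1, c(1, 1, 2)), w2), "1x1")
})

test_that("attention multipliers stay in (1,3) across random forward passes", {
  rec <- new.env(); rec$ranges <- list()
  for (i in 1:34) {
    wc <- withr::with_seed(i, semfuse:::cmam_init(2L, 2L))
    semfuse:::cmam_fwd(semfuse:::ad_node(rand_feat(5, 5, 2, seed = i, sd = 2)),
                       semfuse:::ad_node(rand_feat(5, 5, 2, seed = 100 + i, sd = 2)),
                       wc, rec = rec)
    wb <- withr::with_seed(i, semfuse:::cbam_init(3L, 2L, 2L))
    semfuse:::cbam_fwd(semfuse:::ad_node(rand_feat(5, 5, 3, seed = 200 + i, sd = 2)),
                       wb, rec = rec)
    ws <- withr::with_seed(i, semfuse:::csam_init(2L, 2L, 2L))
    semfuse:::csam_fwd(semfuse:::ad_node(rand_feat(5, 5, 2, seed = 300 + i, sd = 2)),
                       ws, rec = rec)
  }
  expect_gte(length(rec$ranges), 100L)
  rng <- range(unlist(rec$ranges))
  expect_gt(rng[1], 1)
  expect_lt(rng[2], 3)
})

test_that("fusion blocks honour shape and zero-propagation contracts", {
  cfg <- tiny_cfg()
  blk <- withr::with_seed(3, semfuse:::fusion_block_init(4L, 6L, 3L, cfg))
  fa <- lapply(1:3, function(i) rand_feat(8, 8, 4, seed = i))
  fb <- lapply(1:3, function(i) rand_feat(8, 8, 4, seed = 10 + i))
  prev <- rand_feat(4, 4, 6, seed = 99)
  out <- fusion_block_forward(fa, fb, prev, blk, cfg)
  expect_identical(dim(out), c(8L, 8L, 4L))
  # coarsest block: no cross-scale processing even when prev weights exist
  blk4 <- withr::with_seed(3, semfuse:::fusion_block_init(4L, NULL, 3L, cfg))
  out4 <- fusion_block_forward(fa, fb, NULL, blk4, cfg)
  expect_identical(dim(out4), c(8L, 8L, 4L))
  expect_null(blk4$csam)
  # zero weights: output is the activation of zero, i.e. zero
  outz <- fusion_block_forward(fa, fb, prev, zero_weights(blk), cfg)
  expect_equal(outz, array(0, dim(outz)))
  expect_error(fusion_block_forward(fa[1:2], fb[1:2], prev, blk, cfg),
               "branch")
})

test_that("the reconstruction head is sigmoid-bounded with matching size", {
  cfg <- tiny_cfg()
  w <- withr::with_seed(8, semfuse:::recon_init(4L, cfg))
  x <- rand_feat(16, 16, 4, seed = 50, sd = 2)
  out <- reconstruct(x, w, cfg)
  expect_identical(dim(out), c(16L, 16L))
  expect_true(all(out >= 0 & out <= 1))
  expect_equal(reconstruct(x, zero_weights(w), cfg), matrix(0.5, 16, 16))
})

test_that("the full network instantiates five blocks and fuses deterministically", {
  cfg <- tiny_cfg()
  model <- init_model(cfg, seed = 4)
  expect_length(model$fusion$blocks, 5L)
  p <- small_pair(seed = 12)
  f1 <- fuse_images(p, model)
  f2 <- fuse_images(p, model)
  expect_identical(f1, f2)
  expect_identical(dim(f1), dim(p$image_a))
  expect_true(all(f1 >= 0 & f1 <= 1))
})
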