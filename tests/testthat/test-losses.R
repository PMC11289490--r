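test_that("intensity loss matches its definition and symmetry", {
  ct <- rand_img(6, 6, seed = 1)
  mri <- rand_img(6, 6, seed = 2)
  expect_equal(intensity_loss(pmax(ct, mri), ct, mri), 0)
  expect_equal(intensity_loss(matrix(0.5, 2, 2), matrix(0, 2, 2),
                              matrix(0, 2, 2)), 0.5)
  f <- rand_img(6, 6, seed = 3)
  expect_equal(intensity_loss(f, ct, mri), intensity_loss(f, mri, ct))
  expect_error(intensity_loss(f, ct, rand_img(4, 4)), "dimensions")
})

test_that("texture loss vanishes for matching gradients and matches the stencil oracle", {
  cst <- matrix(0.3, 8, 8)
  expect_equal(texture_loss(cst, cst + 0.2, cst - 0.1), 0)
  ct <- rand_img(8, 8, seed = 4)
  expect_equal(texture_loss(ct, ct, cst), 0)
  # checkerboard source, flat fusion: loss equals mean Sobel magnitude
  cb <- outer(1:8, 1:8, function(i, j) (i + j) %% 2)
  expected <- mean(oracle_sobel(cb)[, , 1])
  expect_equal(texture_loss(cst, cb, cst), expected, tolerance = 1e-12)
  f <- rand_img(8, 8, seed = 5)
  expect_equal(texture_loss(f, ct, cb), texture_loss(f, cb, ct))
})

test_that("content loss combines its parts with the balance constant", {
  ct <- rand_img(6, 6, seed = 6)
  mri <- rand_img(6, 6, seed = 7)
  f <- rand_img(6, 6, seed = 8)
  expect_equal(content_loss(f, ct, mri, alpha = 0), intensity_loss(f, ct, mri))
  expect_equal(content_loss(f, ct, mri, alpha = 5),
               intensity_loss(f, ct, mri) + 5 * texture_loss(f, ct, mri))
  expect_equal(content_loss(pmax(ct, ct), ct, ct, alpha = 5), 0)
  expect_error(content_loss(f, ct, mri, alpha = -1), "alpha")
})

test_that("ssim satisfies identity, symmetry and the constant-image closed form", {
  x <- rand_img(16, 16, seed = 9)
  expect_equal(ssim(x, x), 1, tolerance = 1e-9)
  y <- rand_img(16, 16, seed = 10)
  expect_equal(ssim(x, y), ssim(y, x), tolerance = 1e-12)
  # constant images: windows have zero variance, closed form applies
  a <- matrix(0.2, 16, 16); b <- matrix(0.4, 16, 16)
  closed <- (2 * 0.2 * 0.4 + 1e-4) / (0.2^2 + 0.4^2 + 1e-4)
  expect_equal(ssim(a, b), closed, tolerance = 1e-12)
  expect_true(abs(ssim(x, y)) <= 1)
})

test_that("ssim agrees with the windowed loop oracle", {
  x <- rand_img(12, 12, seed = 11)
  y <- rand_img(12, 12, seed = 12)
  expect_equal(ssim(x, y), oracle_ssim(x, y), tolerance = 1e-6)
})

test_that("similarity loss vanishes on identical triples and shrinks toward the sources", {
  p <- small_pair(seed = 20, size = 32L)
  x <- p$image_a
  expect_equal(similarity_loss(x, x, x), 0, tolerance = 1e-9)
  target <- (p$image_a + p$image_b) / 2
  noise <- rand_img(32, 32, seed = 13)
  ts <- seq(0, 1, by = 0.25)
  vals <- vapply(ts, function(t)
    similarity_loss((1 - t) * noise + t * target, p$image_a, p$image_b),
    numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_true(all(vals >= 0 & vals <= 2))
})

test_that("the total loss is the sum of its components", {
  p <- small_pair(seed = 21, size = 32L)
  f <- rand_img(32, 32, seed = 14)
  br <- total_fusion_loss(f, p$image_a, p$image_b, semantic_value = 0.3,
                          alpha = 5)
  expect_equal(br$total, br$content + br$similarity + br$semantic)
  expect_equal(br$content, br$intensity + br$alpha * br$texture)
  expect_equal(br$intensity, intensity_loss(f, p$image_a, p$image_b))
  expect_equal(br$texture, texture_loss(f, p$image_a, p$image_b))
  expect_equal(br$similarity, similarity_loss(f, p$image_a, p$image_b))
  expect_true(all(unlist(br[c("total", "content", "intensity", "texture",
                              "similarity", "semantic")]) >= 0))
  x <- matrix(0.4, 16, 16)
  expect_equal(total_fusion_loss(x, x, x)$total, 0, tolerance = 1e-9)
  expect_error(total_fusion_loss(f, p$image_a, p$image_b, semantic_value = -1),
               "semantic")
})

test_that("loss gradients with respect to the fused image match finite differences", {
  set.seed(31)
  f <- matrix(runif(64, 0.2, 0.8), 8, 8)
  ct <- rand_img(8, 8, seed = 15)
  mri <- rand_img(8, 8, seed = 16)
  tmax <- semfuse:::as_hwc(pmax(ct, mri))
  gmax <- semfuse:::as_hwc(pmax(sobel_gradient(ct), sobel_gradient(mri)))
  cases <- list(
    intensity = list(
      node = function(n) semfuse:::intensity_loss_node(n, tmax),
      num = function(z) intensity_loss(z, ct, mri)),
    texture = list(
      node = function(n) semfuse:::texture_loss_node(n, gmax),
      num = function(z) texture_loss(z, ct, mri)),
    similarity = list(
      node = function(n) semfuse:::similarity_loss_node(
        n, semfuse:::ad_node(semfuse:::as_hwc(ct)),
        semfuse:::ad_node(semfuse:::as_hwc(mri))),
      num = function(z) similarity_loss(z, ct, mri))
  )
  for (nm in names(cases)) {
    leaf <- semfuse:::ad_leaf(semfuse:::as_hwc(f))
    semfuse:::ad_backward(cases[[nm]]$node(leaf))
    g <- semfuse:::ad_grad(leaf)[, , 1]
    gn <- fd_gradient(cases[[nm]]$num, f, eps = 1e-5)
    expect_lt(max(abs(g - gn)) / max(abs(gn)), 1e-3)
  }
})
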