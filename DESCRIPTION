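Package: semfuse
Title: Semantic-Aware Multimodal Medical Image Fusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fuses registered pairs of single-channel medical images
    (CT-like and MRI-like) with a multi-branch, multi-scale convolutional
    network built on Sobel-gradient feature blocks and cross-modal,
    cross-branch and cross-scale attention. Training combines an
    intensity, texture and structural-similarity loss with a semantic
    loss obtained from an unsupervised per-pixel clustering segmentation
    network, the two networks being trained in alternation. Includes a
    seeded generator of registered two-modality brain-like phantoms, the
    eight fusion quality metrics commonly used in the field (PSNR, AG,
    SF, VIF, Qabf, Nabf, SSIM, MS-SSIM), and a small reverse-mode
    automatic differentiation engine in base R that powers the networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    png,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
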