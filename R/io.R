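# Grayscale image input/output. Readers accept 8/16-bit single-channel
# PNG or TIFF (color inputs are converted to BT.601 luminance, optionally
# keeping chroma for re-attachment after fusion); writers quantize with
# round-half-up at the requested bit depth. 16-bit output uses TIFF;
# PNG output is 8-bit with the writers available here.

img_ext <- function(path) tolower(tools::file_ext(path))

#' Read a grayscale image
#'
#' @param path 8/16-bit PNG or TIFF file; 3- or 4-channel images are
#'   converted to luminance.
#' @param keep_chroma attach the Cb/Cr chroma planes of a color input as
#'   attribute `"chroma"` so [recolor()] can restore color after fusion.
#' @return H x W matrix in \[0,1\].
#' @export
read_gray <- function(path, keep_chroma = FALSE) {
  if (!file.exists(path)) stop(sprintf("cannot read image: %s", path))
  ext <- img_ext(path)
  img <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stop(sprintf("unsupported image format '%s': %s", ext, path)))
  if (length(img) == 0L) stop(sprintf("zero-sized image: %s", path))
  chroma <- NULL
  if (length(dim(img)) == 3L) {
    if (dim(img)[3L] >= 3L) {
      r <- img[, , 1L]; g <- img[, , 2L]; b <- img[, , 3L]
      y <- 0.299 * r + 0.587 * g + 0.114 * b
      if (keep_chroma) chroma <- list(cb = (b - y) * 0.564, cr = (r - y) * 0.713)
      img <- y
    } else img <- img[, , 1L]
  }
  img <- pmin(pmax(img, 0), 1)
  if (!is.null(chroma)) attr(img, "chroma") <- chroma
  img
}

#' Re-attach chroma planes to a fused luminance image
#'
#' @param gray H x W luminance matrix in \[0,1\].
#' @param chroma chroma list as attached by [read_gray()].
#' @return (H, W, 3) RGB array in \[0,1\].
#' @export
recolor <- function(gray, chroma) {
  r <- gray + 1.403 * chroma$cr
  b <- gray + 1.773 * chroma$cb
  g <- (gray - 0.299 * r - 0.114 * b) / 0.587
  out <- array(0, c(nrow(gray), ncol(gray), 3L))
  out[, , 1L] <- r; out[, , 2L] <- g; out[, , 3L] <- b
  pmin(pmax(out, 0), 1)
}

#' Write a grayscale image
#'
#' Values are quantized with round-half-up at the requested bit depth and
#' stored losslessly. 16-bit output requires TIFF.
#'
#' @param image H x W matrix in \[0,1\]; out-of-range values are an error.
#' @param path output path ending in .png, .tif or .tiff.
#' @param bitdepth 8 or 16 (default 16 for TIFF, 8 for PNG).
#' @export
write_gray <- function(image, path, bitdepth = NULL) {
  if (any(image < 0 | image > 1))
    stop("write_gray: image values must lie in [0,1]")
  ext <- img_ext(path)
  if (is.null(bitdepth)) bitdepth <- if (ext == "png") 8L else 16L
  if (!bitdepth %in% c(8L, 16L)) stop("write_gray: bitdepth must be 8 or 16")
  mx <- 2^bitdepth - 1
  q <- floor(image * mx + 0.5) / mx
  switch(ext,
         png = {
           if (bitdepth == 16L)
             stop("write_gray: 16-bit output requires TIFF (.tif)")
           png::writePNG(q, path)
         },
         tif = ,
         tiff = tiff::writeTIFF(q, path, bits.per.sample = bitdepth,
                                compression = "none"),
         stop(sprintf("unsupported image format '%s': %s", ext, path)))
  invisible(path)
}
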