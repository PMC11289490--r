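# Seeded generator of registered two-modality brain-like phantoms.
#
# Modality A emulates CT contrast: a dense bright elliptical ring (skull)
# and a few small hyper-intense foci (calcifications) over a dim interior.
# Modality B emulates MRI contrast: a dark ring, richly textured interior
# (soft tissue) and larger high-signal masses (lesions). Each feature is
# visible predominantly in one modality, so a good fusion must take the
# ring and foci from A and the texture and masses from B. A ground-truth
# region map (background / ring / tissue / focus / mass) is emitted for
# sanity checks of the unsupervised segmentation.

#' Phantom generation parameters
#'
#' @param height,width image size in pixels (>= 32).
#' @param n_foci_a number of small bright foci in modality A.
#' @param n_masses_b number of high-signal masses in modality B.
#' @param texture_scale_b spatial correlation length (pixels) of the
#'   modality-B interior texture (Gaussian-blurred white noise).
#' @param ring_width ring thickness in pixels.
#' @param noise_sd standard deviation of additive Gaussian noise
#'   (intensity units), applied to both modalities before clipping.
#' @param seed integer RNG seed; identical specs give identical phantoms.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(height = 256L, width = 256L, n_foci_a = 4L,
                         n_masses_b = 2L, texture_scale_b = 6,
                         ring_width = 6, noise_sd = 0.01, seed = 1L) {
  spec <- list(height = as.integer(height), width = as.integer(width),
               n_foci_a = as.integer(n_foci_a),
               n_masses_b = as.integer(n_masses_b),
               texture_scale_b = texture_scale_b,
               ring_width = ring_width, noise_sd = noise_sd,
               seed = as.integer(seed))
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

validate_phantom_spec <- function(spec) {
  if (!is_count(spec$height) || !is_count(spec$width) ||
      spec$height < 32L || spec$width < 32L)
    stop_config("phantom dimensions must be integers >= 32")
  if (!is_count(spec$n_foci_a) || !is_count(spec$n_masses_b))
    stop_config("feature counts must be non-negative integers")
  if (!is.numeric(spec$noise_sd) || spec$noise_sd < 0)
    stop_config("noise_sd must be >= 0")
  if (spec$texture_scale_b <= 0) stop_config("texture_scale_b must be > 0")
  if (spec$ring_width < 1) stop_config("ring_width must be >= 1")
  invisible(spec)
}

#' Region-map label codes
#' @export
phantom_labels <- function() {
  c(background = 0L, ring = 1L, tissue = 2L, focus = 3L, mass = 4L)
}

#' Generate one registered phantom pair
#'
#' @param spec a [phantom_spec()].
#' @return list of class `registered_pair` with `image_a`, `image_b`
#'   (H x W matrices in \[0,1\]) and `region_map` (H x W integer matrix,
#'   see [phantom_labels()]).
#' @export
generate_pair <- function(spec) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  validate_phantom_spec(spec)
  with_seed(spec$seed, generate_pair_impl(spec))
}

generate_pair_impl <- function(spec) {
  H <- spec$height; W <- spec$width
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  ry <- 0.40 * H; rx <- 0.38 * W
  r <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  dnorm_ <- sqrt(((r - cy) / ry)^2 + ((cc - cx) / rx)^2)
  half_band <- spec$ring_width / 2 / min(rx, ry)
  ring <- abs(dnorm_ - 1) <= half_band
  interior <- dnorm_ < 1 - half_band

  lab <- phantom_labels()
  region <- matrix(lab[["background"]], H, W)
  region[interior] <- lab[["tissue"]]
  region[ring] <- lab[["ring"]]

  image_a <- matrix(0.05, H, W)
  image_a[ring] <- 0.92

  # textured soft tissue for modality B
  sigma <- spec$texture_scale_b
  ksz <- min(2L * ceiling(2 * sigma) + 1L, 2L * (min(H, W) %/% 2L) - 1L)
  tex <- dwconv_num(matrix(stats::rnorm(H * W), H, W), gaussian_kernel(ksz, sigma))[, , 1L]
  tex <- (tex - min(tex)) / max(max(tex) - min(tex), 1e-12)
  image_b <- matrix(0.05, H, W)
  image_b[interior] <- 0.25 + 0.35 * tex[interior]
  image_b[ring] <- 0.12

  # place circular features inside the brain, foci and masses disjoint
  margin <- 1 - half_band - 0.15
  place <- function(n, rad_lo, rad_hi, taken, min_gap) {
    out <- NULL
    tries <- 0L
    while (is.null(dim(out)) || nrow(out) < n) {
      tries <- tries + 1L
      if (tries > 5000L)
        stop_config("could not place %d features; phantom too small or crowded", n)
      rad <- stats::runif(1, rad_lo, rad_hi)
      py <- cy + (2 * stats::runif(1) - 1) * ry * margin
      px <- cx + (2 * stats::runif(1) - 1) * rx * margin
      if (sqrt(((py - cy) / ry)^2 + ((px - cx) / rx)^2) > margin) next
      all_pts <- rbind(taken, out)
      if (!is.null(all_pts) && nrow(all_pts) > 0 &&
          any(sqrt((all_pts[, 1] - py)^2 + (all_pts[, 2] - px)^2) <
              all_pts[, 3] + rad + min_gap)) next
      out <- rbind(out, c(py, px, rad))
    }
    out
  }
  gap <- max(2, 0.015 * min(H, W))
  foci <- if (spec$n_foci_a > 0)
    place(spec$n_foci_a, 1.5, 2.8, NULL, gap) else NULL
  masses <- if (spec$n_masses_b > 0)
    place(spec$n_masses_b, 0.035 * min(H, W), 0.07 * min(H, W), foci, gap) else NULL

  if (!is.null(foci)) for (i in seq_len(nrow(foci))) {
    disc <- (r - foci[i, 1])^2 + (cc - foci[i, 2])^2 <= foci[i, 3]^2
    image_a[disc] <- 0.98
    region[disc] <- lab[["focus"]]
  }
  if (!is.null(masses)) for (i in seq_len(nrow(masses))) {
    disc <- (r - masses[i, 1])^2 + (cc - masses[i, 2])^2 <= masses[i, 3]^2
    image_b[disc] <- 0.90
    region[disc] <- lab[["mass"]]
  }

  if (spec$noise_sd > 0) {
    image_a <- image_a + matrix(stats::rnorm(H * W, sd = spec$noise_sd), H, W)
    image_b <- image_b + matrix(stats::rnorm(H * W, sd = spec$noise_sd), H, W)
  }
  image_a <- pmin(pmax(image_a, 0), 1)
  image_b <- pmin(pmax(image_b, 0), 1)
  storage.mode(region) <- "integer"
  structure(list(image_a = image_a, image_b = image_b, region_map = region,
                 spec = spec),
            class = "registered_pair")
}

#' Generate a dataset of registered phantom pairs
#'
#' Pair `i` uses seed `spec$seed + i - 1`; the manifest records ids, seeds
#' and (when `dir` is given) file paths. Images are written as 16-bit
#' grayscale TIFF, region maps as 8-bit PNG, the manifest as
#' `manifest.csv`.
#'
#' @param n number of pairs (>= 1).
#' @param spec a [phantom_spec()] used as the template.
#' @param dir optional output directory; created if missing.
#' @return list with `pairs` (list of `registered_pair`) and `manifest`
#'   (data.frame).
#' @export
generate_dataset <- function(n, spec = phantom_spec(), dir = NULL) {
  if (!is_count(n) || n < 1) stop_config("n must be an integer >= 1")
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  pairs <- vector("list", n)
  ids <- sprintf("phantom%03d", seq_len(n))
  seeds <- spec$seed + seq_len(n) - 1L
  for (i in seq_len(n)) {
    sp <- spec
    sp$seed <- seeds[i]
    pairs[[i]] <- generate_pair(sp)
  }
  manifest <- data.frame(id = ids, seed = seeds,
                         path_a = NA_character_, path_b = NA_character_,
                         path_map = NA_character_,
                         stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_len(n)) {
      pa <- file.path(dir, paste0(ids[i], "_A.tif"))
      pb <- file.path(dir, paste0(ids[i], "_B.tif"))
      pm <- file.path(dir, paste0(ids[i], "_map.png"))
      write_gray(pairs[[i]]$image_a, pa, bitdepth = 16L)
      write_gray(pairs[[i]]$image_b, pb, bitdepth = 16L)
      png::writePNG(pairs[[i]]$region_map / 255, pm)
      manifest$path_a[i] <- pa
      manifest$path_b[i] <- pb
      manifest$path_map[i] <- pm
    }
    utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  list(pairs = pairs, manifest = manifest)
}

#' @export
print.registered_pair <- function(x, ...) {
  cat(sprintf("registered phantom pair %dx%d (seed %d)\n",
              nrow(x$image_a), ncol(x$image_a), x$spec$seed))
  tab <- table(factor(x$region_map, levels = phantom_labels(),
                      labels = names(phantom_labels())))
  print(tab)
  invisible(x)
}
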