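# Synthetic fluorescence-like texture images.
#
# Five pattern families emulate the micro-textures that distinguish
# subcellular phenotype classes in fluorescence microscopy: filamentous
# (cytoskeleton-like oriented ridges), punctate (vesicle-like spots), blob
# (nucleus-like smooth peaks), reticular (ER-like correlated mesh), and ring
# (nucleolus/membrane-like annuli).  Intensities live on [0, 1] and are
# quantized to the 16-bit grid so that images survive a TIFF round trip
# bit-for-bit.

.gauss_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  H <- nrow(img); W <- ncol(img)
  out <- matrix(0, H, W)
  for (o in -r:r)
    out <- out + k[o + r + 1] * img[pmin(pmax(seq_len(H) + o, 1), H), , drop = FALSE]
  img2 <- out
  out <- matrix(0, H, W)
  for (o in -r:r)
    out <- out + k[o + r + 1] * img2[, pmin(pmax(seq_len(W) + o, 1), W), drop = FALSE]
  out
}

.synth_families <- c("filament", "punctate", "blob", "reticular", "ring")

.synth_defaults <- function(family) {
  common <- list(background = 0.1, noise_sigma = 0.05, poisson_scale = 0,
                 intensity_range = c(0, 1))
  fam <- switch(family,
    filament = list(n_segments = 25, orientation = 45, orientation_spread = 20,
                    seg_length = 40, blur = 1.2, amplitude = 0.8),
    punctate = list(density = 30, spot_sigma = 1.5, amp_min = 0.5, amp_max = 1),
    blob = list(n_blobs = 2, blob_scale = 20, amplitude = 0.9),
    reticular = list(corr_length = 4, amplitude = 0.8),
    ring = list(n_rings = 8, ring_radius = 7, ring_radius_jitter = 3,
                ring_width = 1.5, amplitude = 0.8))
  c(fam, common)
}

#' Specify one synthetic texture class
#'
#' @param name class label.
#' @param family pattern family: `"filament"`, `"punctate"`, `"blob"`,
#'   `"reticular"` or `"ring"`.
#' @param ... family parameter overrides; see the package vignette for the
#'   full parameter table and valid ranges.
#' @return object of class `"synthetic_class_spec"`.
#' @export
synthetic_class_spec <- function(name, family, ...) {
  family <- match.arg(family, .synth_families)
  params <- .synth_defaults(family)
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(params))
      stop(sprintf("unknown parameter '%s' for family '%s'", nm, family))
    params[[nm]] <- over[[nm]]
  }
  chk <- function(field, ok) if (!ok) stop(sprintf("invalid value for field '%s'", field))
  chk("background", params$background >= 0 && params$background < 1)
  chk("noise_sigma", params$noise_sigma >= 0)
  chk("poisson_scale", params$poisson_scale >= 0)
  chk("intensity_range", length(params$intensity_range) == 2 &&
        params$intensity_range[1] < params$intensity_range[2])
  if (family == "punctate") chk("density", params$density >= 0)
  if (family == "filament") chk("n_segments", params$n_segments >= 1)
  if (family == "reticular") chk("corr_length", params$corr_length > 0)
  if (family == "ring") chk("ring_radius", params$ring_radius > 0)
  if (family == "blob") chk("blob_scale", params$blob_scale > 0)
  structure(list(name = name, family = family, params = params),
            class = "synthetic_class_spec")
}

#' Default five-class phenotype specification
#'
#' One spec per family at the documented default parameters.  Four classes
#' are well separated by micro-texture alone; the defaults also keep one
#' deliberately confusable pairing (the small blurred annuli of the ring
#' class share local structure with spot-like patterns, and the blob class
#' carries almost no micro-texture), mirroring the near-identical phenotype
#' pairs seen in real collections.
#'
#' @return named list of five [synthetic_class_spec()] objects.
#' @export
default_class_specs <- function() {
  specs <- list(
    synthetic_class_spec("filamentous", "filament"),
    synthetic_class_spec("punctate", "punctate"),
    synthetic_class_spec("blob", "blob"),
    synthetic_class_spec("reticular", "reticular"),
    synthetic_class_spec("ring", "ring"))
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}

.draw_spots <- function(img, xs, ys, sigma, amps) {
  side <- nrow(img)
  r <- max(2L, ceiling(3 * sigma))
  ax <- -r:r
  kernel <- exp(-outer(ax^2, ax^2, "+") / (2 * sigma^2))
  for (s in seq_along(xs)) {
    cx <- round(xs[s]); cy <- round(ys[s])
    rows <- (cy - r):(cy + r); cols <- (cx - r):(cx + r)
    ok_r <- rows >= 1 & rows <= side; ok_c <- cols >= 1 & cols <= side
    img[rows[ok_r], cols[ok_c]] <- img[rows[ok_r], cols[ok_c]] +
      amps[s] * kernel[ok_r, ok_c]
  }
  img
}

#' Generate one synthetic grayscale image
#'
#' Deterministic given `(spec, side, seed)`.  The pattern is drawn on a
#' constant background, blurred per family, additive Gaussian noise of the
#' spec's `noise_sigma` (plus optional signal-dependent noise scaled by
#' `poisson_scale`) is applied, and intensities are clamped to the spec's
#' range and quantized to the 16-bit grid.
#'
#' @param spec a [synthetic_class_spec()].
#' @param side image side in pixels (>= 64).
#' @param seed RNG seed.
#' @return numeric matrix `side` x `side` with values in `[0, 1]`.
#' @export
generate_image <- function(spec, side = 128L, seed = 0L) {
  stopifnot(inherits(spec, "synthetic_class_spec"))
  if (side < 64) stop("side must be at least 64 pixels")
  set.seed(seed)
  p <- spec$params
  img <- matrix(p$background, side, side)
  n_elements <- 0L
  if (spec$family == "filament") {
    n <- max(1L, stats::rpois(1, p$n_segments))
    n_elements <- n
    for (s in seq_len(n)) {
      theta <- (p$orientation + stats::rnorm(1, sd = p$orientation_spread)) * pi / 180
      cx <- stats::runif(1, 1, side); cy <- stats::runif(1, 1, side)
      tt <- seq(-p$seg_length / 2, p$seg_length / 2, by = 0.5)
      xs <- round(cx + tt * cos(theta)); ys <- round(cy + tt * sin(theta))
      ok <- xs >= 1 & xs <= side & ys >= 1 & ys <= side
      img[cbind(ys[ok], xs[ok])] <- img[cbind(ys[ok], xs[ok])] + p$amplitude
    }
    img <- .gauss_blur(img, p$blur)
  } else if (spec$family == "punctate") {
    n <- stats::rpois(1, p$density)
    n_elements <- n
    if (n > 0) {
      xs <- stats::runif(n, 1, side); ys <- stats::runif(n, 1, side)
      amps <- stats::runif(n, p$amp_min, p$amp_max)
      img <- .draw_spots(img, xs, ys, p$spot_sigma, amps)
    }
  } else if (spec$family == "blob") {
    n_elements <- p$n_blobs
    for (s in seq_len(p$n_blobs)) {
      cx <- stats::runif(1, side * 0.25, side * 0.75)
      cy <- stats::runif(1, side * 0.25, side * 0.75)
      ax <- seq_len(side)
      img <- img + p$amplitude *
        exp(-outer((ax - cy)^2, (ax - cx)^2, "+") / (2 * p$blob_scale^2))
    }
  } else if (spec$family == "reticular") {
    noise <- matrix(stats::rnorm(side * side), side, side)
    band <- .gauss_blur(noise, p$corr_length) - .gauss_blur(noise, 3 * p$corr_length)
    band <- band / max(stats::sd(band), 1e-12)
    img <- img + p$amplitude * 0.25 * band + p$amplitude * 0.25
  } else if (spec$family == "ring") {
    n <- max(1L, stats::rpois(1, p$n_rings))
    n_elements <- n
    ring <- matrix(0, side, side)
    for (s in seq_len(n)) {
      rad <- p$ring_radius + stats::runif(1, -p$ring_radius_jitter, p$ring_radius_jitter)
      rad <- max(2, rad)
      cx <- stats::runif(1, 1, side); cy <- stats::runif(1, 1, side)
      ang <- seq(0, 2 * pi, length.out = max(16, ceiling(2 * pi * rad * 2)))
      xs <- round(cx + rad * cos(ang)); ys <- round(cy + rad * sin(ang))
      ok <- xs >= 1 & xs <= side & ys >= 1 & ys <= side
      ring[cbind(ys[ok], xs[ok])] <- p$amplitude
    }
    img <- img + .gauss_blur(ring, p$ring_width)
  }
  if (p$noise_sigma > 0)
    img <- img + matrix(stats::rnorm(side * side, sd = p$noise_sigma), side, side)
  if (p$poisson_scale > 0)
    img <- img + sqrt(pmax(img, 0)) * p$poisson_scale *
      matrix(stats::rnorm(side * side), side, side)
  img <- pmin(pmax(img, p$intensity_range[1]), p$intensity_range[2])
  img <- round(img * 65535) / 65535
  attr(img, "n_elements") <- n_elements
  img
}

#' Generate a balanced labeled dataset
#'
#' Per-image seeds are derived deterministically from the master seed, so
#' the full dataset is a pure function of `(specs, n_per_class, side,
#' seed)`.  With `dir` given, images are also written as 16-bit grayscale
#' TIFFs into one subdirectory per class plus a `manifest.csv`, the same
#' layout the dataset scanner expects.
#'
#' @param specs list of [synthetic_class_spec()] objects (>= 2, unique names).
#' @param n_per_class images per class.
#' @param side image side in pixels.
#' @param seed master seed.
#' @param dir optional output directory.
#' @return list with `images` (named list of matrices), `labels` (factor)
#'   and `manifest` (data frame of image_id, label, seed, and path if
#'   written).
#' @export
generate_dataset <- function(specs, n_per_class = 40L, side = 128L, seed = 0L,
                             dir = NULL) {
  if (length(specs) < 2) stop("need at least 2 class specs")
  if (n_per_class < 1) stop("n_per_class must be >= 1")
  nms <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("duplicate class names in specs")
  images <- list(); labels <- character(0); rows <- list()
  for (ci in seq_along(specs)) {
    for (i in seq_len(n_per_class)) {
      img_seed <- (as.numeric(seed) * 7919 + ci * 100003 + i) %% 2147483647
      id <- sprintf("%s_%03d", nms[ci], i)
      images[[id]] <- generate_image(specs[[ci]], side = side, seed = img_seed)
      labels <- c(labels, nms[ci])
      rows[[id]] <- data.frame(image_id = id, label = nms[ci], seed = img_seed)
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- character(nrow(manifest))
    for (r in seq_len(nrow(manifest))) {
      cls_dir <- file.path(dir, manifest$label[r])
      dir.create(cls_dir, showWarnings = FALSE)
      paths[r] <- file.path(cls_dir, paste0(manifest$image_id[r], ".tif"))
      tiff::writeTIFF(images[[manifest$image_id[r]]], paths[r],
                      bits.per.sample = 16L)
    }
    manifest$path <- paths
    utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  list(images = images, labels = factor(labels, levels = nms),
       manifest = manifest)
}
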