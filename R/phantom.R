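# Synthetic CT-like kidney phantoms: labeled images with paired lesion masks.

#' Kidney condition class labels
#'
#' The four conditions handled throughout the package, in canonical order.
#' This order is also the tie-break order for largest-remainder class-count
#' assignment in [generate_dataset()].
#' @export
kidney_classes <- c("normal", "cyst", "stone", "tumor")

#' Phantom generator specification
#'
#' Describes the synthetic abdominal-CT-like phantom: a noisy soft-tissue
#' background, an elliptical kidney region, and one class-specific lesion.
#' Intensities are generated in arbitrary units and (by default) min-max
#' normalized to `[0, 1]`, matching the preprocessing the networks expect.
#'
#' Lesion appearance follows typical CT contrast: cysts are round hypodense
#' (darker) blobs, stones are small hyperdense (bright) blobs, tumors are
#' larger irregular multi-lobed regions of mildly elevated, heterogeneous
#' intensity. `normal` phantoms carry no lesion and an all-zero mask.
#'
#' @param image_size Pixels per side (square image). Default 46, the input
#'   plane of the multi-stream network.
#' @param background_noise_sd Standard deviation of additive Gaussian
#'   background noise, in intensity units.
#' @param kidney_axes Length-2 numeric, semi-axes (pixels) of the elliptical
#'   kidney region (row, column).
#' @param lesion_params Named list (`cyst`, `stone`, `tumor`), each with
#'   `radius = c(min, max)` in pixels and `offset` (additive intensity).
#' @param normalize Logical; min-max scale the final image to `[0, 1]`.
#' @return An object of class `phantom_spec`.
#' @seealso [generate_phantom()], [generate_dataset()]
#' @export
phantom_spec <- function(image_size = 46L,
                         background_noise_sd = 0.05,
                         kidney_axes = c(14, 9),
                         lesion_params = list(
                           cyst  = list(radius = c(3, 6), offset = -0.25),
                           stone = list(radius = c(1, 3), offset = 0.40),
                           tumor = list(radius = c(4, 7), offset = 0.15)
                         ),
                         normalize = TRUE) {
  image_size <- as.integer(image_size)
  if (image_size < 8L) stop("`image_size` must be at least 8 pixels")
  if (background_noise_sd < 0) stop("`background_noise_sd` must be >= 0")
  radii <- c(kidney_axes, unlist(lapply(lesion_params, `[[`, "radius")))
  if (any(radii >= image_size / 2))
    stop("all radii/axes must be smaller than image_size/2")
  structure(list(image_size = image_size,
                 background_noise_sd = background_noise_sd,
                 kidney_axes = kidney_axes,
                 lesion_params = lesion_params,
                 normalize = normalize),
            class = "phantom_spec")
}

new_labeled_sample <- function(image, mask, label) {
  stopifnot(identical(dim(image), dim(mask)))
  if (!all(mask %in% c(0L, 1L))) stop("mask values must be 0 or 1")
  if (label == "normal" && any(mask != 0L))
    stop("a 'normal' sample must have an all-zero mask")
  structure(list(image = image, mask = mask, label = label),
            class = "labeled_sample")
}

#' @export
print.labeled_sample <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<labeled_sample> %dx%d, label '%s', %d lesion pixel(s)\n",
              d[1], d[2], x$label, sum(x$mask)))
  invisible(x)
}

#' Generate one labeled kidney phantom
#'
#' Deterministic for a fixed `(spec, label, seed)` triple: all randomness is
#' drawn from a private stream seeded with `seed`, and the global RNG state
#' is left untouched.
#'
#' @param spec A [phantom_spec()].
#' @param label One of `r paste0('"', kidney_classes, '"', collapse = ", ")`.
#' @param seed Non-negative integer seed.
#' @return A `labeled_sample`: `image` (matrix in `[0, 1]`), `mask`
#'   (integer matrix, 1 = lesion), `label`.
#' @examples
#' p <- generate_phantom(phantom_spec(), "cyst", seed = 1)
#' sum(p$mask) > 0
#' @export
generate_phantom <- function(spec = phantom_spec(), label, seed) {
  if (!is.character(label) || length(label) != 1L || !label %in% kidney_classes)
    stop(sprintf("unknown label %s; must be one of: %s",
                 deparse(label), paste(kidney_classes, collapse = ", ")),
         call. = FALSE)
  stopifnot(inherits(spec, "phantom_spec"))
  with_rng(seed, {
    s <- spec$image_size
    rr <- matrix(seq_len(s), s, s)
    cc <- matrix(seq_len(s), s, s, byrow = TRUE)
    ctr <- (s + 1) / 2
    img <- 0.15 + 0.04 * (rr / s) +
      matrix(stats::rnorm(s * s, 0, spec$background_noise_sd), s, s)
    body <- ((rr - ctr) / (0.46 * s))^2 + ((cc - ctr) / (0.42 * s))^2 <= 1
    img[body] <- img[body] + 0.22
    kc <- ctr + stats::runif(2, -0.04 * s, 0.04 * s)
    ka <- spec$kidney_axes
    kid <- ((rr - kc[1]) / ka[1])^2 + ((cc - kc[2]) / ka[2])^2 <= 1
    img[kid] <- img[kid] + 0.14
    mask <- matrix(0L, s, s)
    if (label != "normal") {
      lp <- spec$lesion_params[[label]]
      lc <- kc + c(stats::runif(1, -0.45, 0.45) * ka[1],
                   stats::runif(1, -0.45, 0.45) * ka[2])
      if (label == "tumor") {
        # irregular lesion: union of 2-4 overlapping discs, jittered centers
        nlobe <- sample(2:4, 1)
        les <- matrix(FALSE, s, s)
        for (l in seq_len(nlobe)) {
          c_l <- lc + stats::runif(2, -2.5, 2.5)
          r_l <- stats::runif(1, lp$radius[1] * 0.55, lp$radius[2] * 0.75)
          les <- les | ((rr - c_l[1])^2 + (cc - c_l[2])^2 <= r_l^2)
        }
      } else {
        r_l <- stats::runif(1, lp$radius[1], lp$radius[2])
        les <- (rr - lc[1])^2 + (cc - lc[2])^2 <= r_l^2
      }
      img[les] <- img[les] + lp$offset
      if (label == "tumor")
        img[les] <- img[les] + stats::rnorm(sum(les), 0, 0.03)
      mask[les] <- 1L
    }
    img <- clamp(img, 0, 1.5)
    if (spec$normalize) {
      rng <- range(img)
      if (rng[2] > rng[1]) img <- (img - rng[1]) / (rng[2] - rng[1])
    } else {
      img <- clamp(img, 0, 1)
    }
    new_labeled_sample(img, mask, label)
  })
}

# Sample img at (possibly fractional) source coordinates; outside -> 0.
px_at <- function(img, r, c) {
  out <- numeric(length(r))
  ok <- r >= 1 & r <= nrow(img) & c >= 1 & c <= ncol(img)
  out[ok] <- img[cbind(r[ok], c[ok])]
  out
}

resample_bilinear <- function(img, sr, sc) {
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0;   fc <- sc - c0
  v <- (1 - fr) * (1 - fc) * px_at(img, r0, c0) +
       (1 - fr) * fc       * px_at(img, r0, c0 + 1) +
       fr       * (1 - fc) * px_at(img, r0 + 1, c0) +
       fr       * fc       * px_at(img, r0 + 1, c0 + 1)
  matrix(v, nrow(img), ncol(img))
}

resample_nearest <- function(img, sr, sc) {
  matrix(px_at(img, round(sr), round(sc)), nrow(img), ncol(img))
}

#' Apply one geometric augmentation to a labeled sample
#'
#' Image and mask receive the identical transform; the image is resampled
#' bilinearly and re-clamped to `[0, 1]`, the mask with nearest-neighbor so
#' it stays binary. The class label is unchanged. Coordinates are (row, col),
#' origin top-left; `translate` uses `dx` = column (x) shift and `dy` = row
#' (y) shift, so `translate` with `dx = 3` moves a pixel at (10, 10) to
#' (10, 13). Regions mapped from outside the frame are filled with 0.
#'
#' @param sample A `labeled_sample`.
#' @param op One of `"rotate"`, `"scale"`, `"flip"`, `"translate"`.
#' @param angle Rotation angle in degrees (for `"rotate"`).
#' @param factor Scale factor > 0 about the image center (for `"scale"`).
#' @param axis `"horizontal"` (mirror left-right) or `"vertical"` (mirror
#'   top-bottom), for `"flip"`.
#' @param dx,dy Column/row shift in pixels (for `"translate"`).
#' @return A transformed `labeled_sample`.
#' @export
augment <- function(sample, op = c("rotate", "scale", "flip", "translate"),
                    angle = NULL, factor = NULL,
                    axis = c("horizontal", "vertical"), dx = 0, dy = 0) {
  stopifnot(inherits(sample, "labeled_sample"))
  op <- match.arg(op)
  img <- sample$image
  msk <- sample$mask
  h <- nrow(img); w <- ncol(img)
  if (op == "flip") {
    axis <- match.arg(axis)
    if (axis == "horizontal") {
      img <- img[, rev(seq_len(w)), drop = FALSE]
      msk <- msk[, rev(seq_len(w)), drop = FALSE]
    } else {
      img <- img[rev(seq_len(h)), , drop = FALSE]
      msk <- msk[rev(seq_len(h)), , drop = FALSE]
    }
  } else {
    rr <- matrix(seq_len(h), h, w)
    cc <- matrix(seq_len(w), h, w, byrow = TRUE)
    ctr_r <- (h + 1) / 2; ctr_c <- (w + 1) / 2
    if (op == "translate") {
      sr <- rr - dy; sc <- cc - dx
    } else if (op == "rotate") {
      if (is.null(angle)) stop("`angle` is required for op = 'rotate'")
      a <- angle * pi / 180
      yr <- rr - ctr_r; xc <- cc - ctr_c
      sr <- ctr_r + cos(a) * yr + sin(a) * xc
      sc <- ctr_c - sin(a) * yr + cos(a) * xc
    } else { # scale
      if (is.null(factor) || !is.finite(factor) || factor <= 0)
        stop("scale `factor` must be > 0")
      sr <- ctr_r + (rr - ctr_r) / factor
      sc <- ctr_c + (cc - ctr_c) / factor
    }
    img <- resample_bilinear(img, sr, sc)
    msk <- resample_nearest(msk, sr, sc)
  }
  img <- clamp(img, 0, 1)
  msk <- matrix(as.integer(msk > 0.5), h, w)
  if (sample$label == "normal") msk[] <- 0L
  new_labeled_sample(img, msk, sample$label)
}

# Largest-remainder apportionment of n into proportions p (ties: first class
# in `kidney_classes` order wins).
largest_remainder <- function(n, p) {
  base <- floor(n * p)
  rem <- n - sum(base)
  frac <- n * p - base
  ord <- order(-frac, seq_along(frac))
  if (rem > 0) base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  as.integer(base)
}

#' Generate a labeled phantom dataset
#'
#' Class counts follow the largest-remainder rule applied to `class_mix`
#' (ties broken in `kidney_classes` order). Bit-reproducible for a fixed
#' `(n, class_mix, spec, seed)`.
#'
#' @param n Total number of samples (>= 4).
#' @param class_mix Per-class proportions summing to 1; either named by
#'   class or positional in `kidney_classes` order.
#' @param spec A [phantom_spec()].
#' @param seed Non-negative integer; per-sample seeds are derived from it.
#' @return A `phantom_dataset`: `samples` (list of `labeled_sample`),
#'   `manifest` (tibble: filename, label, seed), `counts`, `spec`, `seed`.
#' @export
generate_dataset <- function(n, class_mix = rep(0.25, 4),
                             spec = phantom_spec(), seed = 1) {
  if (n < 4) stop("`n` must be at least 4")
  p <- class_mix
  if (!is.null(names(p))) {
    if (!setequal(names(p), kidney_classes))
      stop("named `class_mix` must use exactly the classes: ",
           paste(kidney_classes, collapse = ", "))
    p <- p[kidney_classes]
  }
  if (length(p) != 4L) stop("`class_mix` must have 4 proportions")
  if (any(p < 0)) stop("class proportions must be non-negative")
  if (abs(sum(p) - 1) > 1e-9) stop("class proportions must sum to 1")
  counts <- stats::setNames(largest_remainder(n, as.numeric(p)), kidney_classes)
  labels <- rep(kidney_classes, counts)
  seeds <- vapply(seq_len(n), function(i) derive_seed(seed, i), integer(1))
  samples <- vector("list", n)
  fnames <- character(n)
  per_class_idx <- stats::setNames(integer(4), kidney_classes)
  for (i in seq_len(n)) {
    lab <- labels[i]
    per_class_idx[lab] <- per_class_idx[lab] + 1L
    samples[[i]] <- generate_phantom(spec, lab, seeds[i])
    fnames[i] <- sprintf("%s_%05d.png", lab, per_class_idx[lab])
  }
  structure(list(
    samples = samples,
    manifest = tibble::tibble(filename = fnames, label = labels, seed = seeds),
    counts = counts, spec = spec, seed = seed
  ), class = "phantom_dataset")
}

#' @export
print.phantom_dataset <- function(x, ...) {
  cat(sprintf("<phantom_dataset> %d samples (seed %d): %s\n",
              length(x$samples), x$seed,
              paste(sprintf("%s=%d", names(x$counts), x$counts), collapse = ", ")))
  invisible(x)
}

#' Write a phantom dataset to disk
#'
#' Images go to `<root>/images/<class>/<name>.png` as 8-bit grayscale PNG
#' (class-folder layout), masks to `<root>/masks/<class>/<name>.png` with
#' values \{0, 255\}, and the manifest to `<root>/manifest.csv`
#' (columns filename, label, seed).
#'
#' @param dataset A `phantom_dataset`.
#' @param root Output directory (created if missing).
#' @return Invisibly, the manifest path.
#' @export
write_phantom_dataset <- function(dataset, root) {
  stopifnot(inherits(dataset, "phantom_dataset"))
  for (cl in kidney_classes) {
    dir.create(file.path(root, "images", cl), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(root, "masks", cl), recursive = TRUE, showWarnings = FALSE)
  }
  if (!dir.exists(root)) stop("cannot create output directory: ", root)
  m <- dataset$manifest
  for (i in seq_along(dataset$samples)) {
    s <- dataset$samples[[i]]
    png::writePNG(s$image, file.path(root, "images", m$label[i], m$filename[i]))
    png::writePNG(s$mask + 0, file.path(root, "masks", m$label[i], m$filename[i]))
  }
  mp <- file.path(root, "manifest.csv")
  utils::write.csv(as.data.frame(m), mp, row.names = FALSE)
  invisible(mp)
}

#' Read a phantom dataset written by [write_phantom_dataset()]
#'
#' @param root Dataset directory containing `manifest.csv`.
#' @return A `phantom_dataset` (spec/seed fields carry only what the
#'   manifest records). PNG round-tripping quantizes intensities to 8 bits.
#' @export
read_phantom_dataset <- function(root) {
  mp <- file.path(root, "manifest.csv")
  if (!file.exists(mp)) stop("no manifest.csv under ", root)
  m <- utils::read.csv(mp, stringsAsFactors = FALSE)
  samples <- lapply(seq_len(nrow(m)), function(i) {
    img <- png::readPNG(file.path(root, "images", m$label[i], m$filename[i]))
    if (length(dim(img)) == 3L) img <- img[, , 1]
    msk <- png::readPNG(file.path(root, "masks", m$label[i], m$filename[i]))
    if (length(dim(msk)) == 3L) msk <- msk[, , 1]
    new_labeled_sample(img, matrix(as.integer(msk > 0.5), nrow(msk), ncol(msk)),
                       m$label[i])
  })
  counts <- table(factor(m$label, levels = kidney_classes))
  structure(list(samples = samples, manifest = tibble::as_tibble(m),
                 counts = stats::setNames(as.integer(counts), kidney_classes),
                 spec = NULL, seed = NA_integer_),
            class = "phantom_dataset")
}
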