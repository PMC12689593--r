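# Seeded generator of class-separable grayscale "atrophy phantom" images.
# Each severity class k is drawn as a centered bright ring around a dark
# cavity; cavity radius and ring thickness grow monotonically with k, a
# ventricle-enlargement proxy for ordinal atrophy grade. The only
# randomness in generation is additive Gaussian noise; geometric variation
# comes from the augmentation operator.

#' Phantom dataset specification
#'
#' @param image_side Canvas side in pixels (even, default 28; the
#'   downstream quanvolution reads only a centered ROI, so large canvases
#'   buy nothing).
#' @param n_classes Number of ordinal severity classes (>= 2, default 4).
#' @param class_proportions Positive proportions summing to 1; the default
#'   `c(0.14, 0.01, 0.50, 0.35)` reproduces the heavy imbalance of a
#'   4-class dementia MRI collection (896/64/3200/2240 at n = 6400).
#' @param noise_sd Standard deviation of additive Gaussian pixel noise
#'   (intensity units; images live in `[0, 1]`).
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return A validated list of class `phantom_spec`.
#' @export
phantom_spec <- function(image_side = 28L, n_classes = 4L,
                         class_proportions = c(0.14, 0.01, 0.50, 0.35),
                         noise_sd = 0.05, seed = 1L) {
  if (!is_count(image_side) || image_side %% 2L != 0L) {
    stop_invalid("image_side must be a positive even integer")
  }
  if (!is_count(n_classes, 2L)) stop_invalid("n_classes must be >= 2")
  if (length(class_proportions) != n_classes || any(class_proportions <= 0)) {
    stop_invalid("class_proportions must be %d positive values", n_classes)
  }
  if (abs(sum(class_proportions) - 1) > 1e-9) {
    stop_invalid("class_proportions must sum to 1 (got %.12f)",
                 sum(class_proportions))
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) stop_invalid("noise_sd must be >= 0")
  structure(list(image_side = as.integer(image_side),
                 n_classes = as.integer(n_classes),
                 class_proportions = as.numeric(class_proportions),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Per-class sample counts from proportions
#'
#' Floor-rounds `n_total * proportion` per class and assigns the remainder
#' to the largest class (deterministic tie-break: first largest).
#'
#' @param spec A `phantom_spec`.
#' @param n_total Total number of images.
#' @return Integer vector of length `n_classes` summing to `n_total`.
#' @export
class_counts <- function(spec, n_total) {
  counts <- floor(n_total * spec$class_proportions)
  rem <- n_total - sum(counts)
  if (rem > 0) {
    big <- which.max(spec$class_proportions)
    counts[big] <- counts[big] + rem
  }
  as.integer(counts)
}

# Noiseless class template: bright elliptical ring with class-monotone
# cavity radius and thickness, on a faint background disc. Geometry is
# scaled by image_side / 28 so larger canvases carry the same structure.
phantom_template <- function(spec, class_k) {
  s <- spec$image_side
  scale <- s / 28
  ctr <- (s + 1) / 2
  yy <- matrix(seq_len(s), s, s) - ctr
  xx <- matrix(seq_len(s), s, s, byrow = TRUE) - ctr
  r <- sqrt(yy^2 + (1.15 * xx)^2)  # mild fixed eccentricity
  r_in <- (1.0 + 1.1 * class_k) * scale
  r_out <- r_in + (1.2 + 0.35 * class_k) * scale
  img <- matrix(0.08, s, s)
  img[r <= r_out + 1.5 * scale] <- 0.35   # parenchyma disc
  img[r > r_in & r <= r_out] <- 0.85      # ring
  img[r <= r_in] <- 0.05                  # cavity ("ventricle")
  img
}

#' Generate a labeled phantom dataset
#'
#' Draws `n_total` images with per-class counts from [class_counts()],
#' adds Gaussian noise of `spec$noise_sd`, clips to `[0, 1]`, and is
#' bit-reproducible from `spec$seed`.
#'
#' @param spec A `phantom_spec`.
#' @param n_total Total images (>= `n_classes`).
#' @return A `labeled_dataset`: list with `images` (`n x side x side`
#'   array in `[0, 1]`), `labels` (0-based integer classes), and
#'   `class_names`.
#' @export
generate_phantoms <- function(spec, n_total) {
  if (!is_count(n_total, spec$n_classes)) {
    stop_invalid("n_total must be an integer >= n_classes (%d)", spec$n_classes)
  }
  counts <- class_counts(spec, n_total)
  labels <- rep(seq_len(spec$n_classes) - 1L, times = counts)
  s <- spec$image_side
  templates <- lapply(seq_len(spec$n_classes) - 1L,
                      function(k) phantom_template(spec, k))
  images <- array(0, dim = c(n_total, s, s))
  with_seed(spec$seed, {
    for (i in seq_len(n_total)) {
      img <- templates[[labels[i] + 1L]]
      if (spec$noise_sd > 0) {
        img <- img + matrix(stats::rnorm(s * s, 0, spec$noise_sd), s, s)
      }
      images[i, , ] <- pmin(pmax(img, 0), 1)
    }
  })
  labeled_dataset(images, labels,
                  class_names = default_class_names(spec$n_classes))
}

default_class_names <- function(n_classes) {
  if (n_classes == 4L) c("mild", "moderate", "non_dementia", "very_mild")
  else paste0("class_", seq_len(n_classes) - 1L)
}

#' Construct a labeled dataset
#'
#' @param images `n x H x W` numeric array with values in `[0, 1]`.
#' @param labels Integer class indices in `[0, n_classes)`.
#' @param class_names Ordered class label strings.
#' @return A list of class `labeled_dataset`.
#' @export
labeled_dataset <- function(images, labels, class_names) {
  if (dim(images)[1L] != length(labels)) {
    stop_invalid("one label per image required (%d images, %d labels)",
                 dim(images)[1L], length(labels))
  }
  if (any(labels < 0L | labels >= length(class_names))) {
    stop_invalid("labels must lie in [0, %d)", length(class_names))
  }
  if (min(images) < 0 || max(images) > 1) {
    stop_invalid("pixel values must lie in [0, 1]")
  }
  structure(list(images = images, labels = as.integer(labels),
                 class_names = class_names),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("<labeled_dataset: %d images, %dx%d, %d classes>\n",
              d[1L], d[2L], d[3L], length(x$class_names)))
  tab <- table(factor(x$labels, levels = seq_along(x$class_names) - 1L,
                      labels = x$class_names))
  print(tab)
  invisible(x)
}

#' Augmentation bounds
#'
#' Defaults are mild standard augmentation: rotation up to ±15 degrees,
#' horizontal flip with probability 0.5, zoom within ±10%, shift within
#' ±10% of the image side.
#'
#' @param rotation Max absolute rotation, degrees.
#' @param flip_p Horizontal-flip probability in `[0, 1]`.
#' @param zoom Max relative zoom deviation (0.1 = ±10%).
#' @param shift Max shift as a fraction of the image side.
#' @return A list of class `aug_limits`.
#' @export
aug_limits <- function(rotation = 15, flip_p = 0.5, zoom = 0.10, shift = 0.10) {
  stopifnot(rotation >= 0, flip_p >= 0, flip_p <= 1, zoom >= 0, zoom < 1,
            shift >= 0)
  structure(list(rotation = rotation, flip_p = flip_p, zoom = zoom,
                 shift = shift),
            class = "aug_limits")
}

# Inverse-mapped affine resample with bilinear interpolation about the
# image centre; out-of-canvas samples read as 0. angle in radians.
affine_sample <- function(img, angle = 0, zoom = 1, dy = 0, dx = 0,
                          flip = FALSE) {
  s <- nrow(img)
  ctr <- (s + 1) / 2
  yy <- matrix(seq_len(s), s, s) - ctr
  xx <- matrix(seq_len(s), s, s, byrow = TRUE) - ctr
  # invert: undo shift, then rotation+zoom, then flip
  yv <- yy - dy; xv <- xx - dx
  ca <- cos(-angle); sa <- sin(-angle)
  ys <- (ca * yv - sa * xv) / zoom + ctr
  xs <- (sa * yv + ca * xv) / zoom + ctr
  if (flip) xs <- (s + 1) - xs
  i0 <- floor(ys); j0 <- floor(xs)
  fy <- ys - i0; fx <- xs - j0
  at <- function(i, j) {
    ok <- i >= 1 & i <= s & j >= 1 & j <= s
    v <- matrix(0, s, s)
    v[ok] <- img[cbind(i[ok], j[ok])]
    v
  }
  out <- (1 - fy) * ((1 - fx) * at(i0, j0) + fx * at(i0, j0 + 1)) +
    fy * ((1 - fx) * at(i0 + 1, j0) + fx * at(i0 + 1, j0 + 1))
  pmin(pmax(out, 0), 1)
}

#' Randomly augment one image
#'
#' Samples a rotation, horizontal flip, zoom and shift uniformly within
#' `limits` from R's current RNG stream (seed it with `set.seed()` for
#' reproducibility) and applies them as a single bilinear affine resample.
#' Output shape equals input shape; values are clipped to `[0, 1]`. All
#' limits at zero yield the identity transform.
#'
#' @param image Numeric matrix with values in `[0, 1]`.
#' @param limits An [aug_limits()] object.
#' @return Augmented matrix, same shape.
#' @export
augment_image <- function(image, limits = aug_limits()) {
  angle <- if (limits$rotation > 0) {
    stats::runif(1, -limits$rotation, limits$rotation) * pi / 180
  } else 0
  flip <- limits$flip_p > 0 && stats::runif(1) < limits$flip_p
  zoom <- if (limits$zoom > 0) stats::runif(1, 1 - limits$zoom, 1 + limits$zoom) else 1
  s <- nrow(image)
  dy <- if (limits$shift > 0) stats::runif(1, -limits$shift, limits$shift) * s else 0
  dx <- if (limits$shift > 0) stats::runif(1, -limits$shift, limits$shift) * s else 0
  if (angle == 0 && !flip && zoom == 1 && dy == 0 && dx == 0) return(image)
  affine_sample(image, angle = angle, zoom = zoom, dy = dy, dx = dx,
                flip = flip)
}

#' Rebalance a dataset to target per-class counts
#'
#' Classes above target are subsampled without replacement; classes below
#' target are topped up with augmented copies of their own members. Label
#' integrity is preserved.
#'
#' @param dataset A `labeled_dataset`.
#' @param target_counts Integer vector of desired per-class counts
#'   (length `n_classes`); a single value is recycled.
#' @param limits Augmentation bounds for the top-up copies.
#' @param seed Integer seed driving subsampling and augmentation.
#' @return A rebalanced `labeled_dataset`, ordered by class.
#' @export
rebalance_dataset <- function(dataset, target_counts, limits = aug_limits(),
                              seed = 1L) {
  K <- length(dataset$class_names)
  if (length(target_counts) == 1L) target_counts <- rep(target_counts, K)
  if (length(target_counts) != K || any(target_counts < 0)) {
    stop_invalid("target_counts must be %d nonnegative integers", K)
  }
  s <- dim(dataset$images)[2L]
  n_out <- sum(target_counts)
  images <- array(0, dim = c(n_out, s, s))
  labels <- integer(n_out)
  pos <- 0L
  with_seed(seed, {
    for (k in seq_len(K) - 1L) {
      members <- which(dataset$labels == k)
      tgt <- target_counts[k + 1L]
      if (tgt == 0L) next
      if (length(members) == 0L) {
        stop_invalid("class %d ('%s') has no source images but target %d",
                     k, dataset$class_names[k + 1L], tgt)
      }
      if (length(members) >= tgt) {
        keep <- members[sample.int(length(members), tgt)]
        for (m in keep) {
          pos <- pos + 1L
          images[pos, , ] <- dataset$images[m, , ]
          labels[pos] <- k
        }
      } else {
        for (m in members) {
          pos <- pos + 1L
          images[pos, , ] <- dataset$images[m, , ]
          labels[pos] <- k
        }
        extra <- tgt - length(members)
        src <- members[sample.int(length(members), extra, replace = TRUE)]
        for (m in src) {
          pos <- pos + 1L
          images[pos, , ] <- augment_image(dataset$images[m, , ], limits)
          labels[pos] <- k
        }
      }
    }
  })
  labeled_dataset(images, labels, dataset$class_names)
}

#' Write / read a dataset as directory-per-class PNGs
#'
#' The on-disk layout is one subdirectory per class name containing
#' 8-bit grayscale PNGs, the layout common to curated MRI-slice
#' collections.
#'
#' @param dataset A `labeled_dataset`.
#' @param dir Output directory (created if missing).
#' @return `read_image_dir` returns a `labeled_dataset` (classes ordered
#'   by sorted subdirectory name).
#' @export
write_image_dir <- function(dataset, dir) {
  for (k in seq_along(dataset$class_names)) {
    sub <- file.path(dir, dataset$class_names[k])
    dir.create(sub, recursive = TRUE, showWarnings = FALSE)
    idx <- which(dataset$labels == k - 1L)
    for (i in seq_along(idx)) {
      png::writePNG(dataset$images[idx[i], , ],
                    file.path(sub, sprintf("img_%05d.png", i)))
    }
  }
  invisible(dir)
}

#' @rdname write_image_dir
#' @param target_side Optional side to resize every image to on read.
#' @export
read_image_dir <- function(dir, target_side = NULL) {
  classes <- sort(list.dirs(dir, recursive = FALSE, full.names = FALSE))
  if (length(classes) == 0L) stop_invalid("no class subdirectories under %s", dir)
  imgs <- list(); labels <- integer()
  for (k in seq_along(classes)) {
    files <- sort(list.files(file.path(dir, classes[k]),
                             pattern = "\\.(png|PNG)$", full.names = TRUE))
    for (f in files) {
      img <- rgb_to_gray(png::readPNG(f))
      if (!is.null(target_side)) img <- resize_bilinear(img, target_side)
      imgs[[length(imgs) + 1L]] <- img
      labels <- c(labels, k - 1L)
    }
  }
  side <- nrow(imgs[[1L]])
  arr <- array(0, dim = c(length(imgs), side, side))
  for (i in seq_along(imgs)) arr[i, , ] <- imgs[[i]]
  labeled_dataset(arr, labels, classes)
}

#' Write / read a dataset as a single compressed archive
#'
#' @param dataset A `labeled_dataset`.
#' @param path Archive file path (`.rds`).
#' @return `read_dataset_archive` returns the `labeled_dataset`.
#' @export
write_dataset_archive <- function(dataset, path) {
  saveRDS(unclass(dataset), path, compress = "gzip")
  invisible(path)
}

#' @rdname write_dataset_archive
#' @export
read_dataset_archive <- function(path) {
  x <- readRDS(path)
  labeled_dataset(x$images, x$labels, x$class_names)
}
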