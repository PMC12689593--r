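# Deterministic image preparation: resize, standardize, centered ROI crop,
# non-overlapping patching, per-patch reduction to the two values fed to the
# 2-qubit encoder. Coordinates are 0-based with half-open ranges; odd crop
# margins are floored.

#' Preprocessing configuration
#'
#' @param target_side Side the input image is resized to before cropping.
#' @param roi_side Side of the centered region of interest (even, default 14).
#' @param patch_side Patch side (default 2, matching the 2-qubit circuit).
#' @param reduction How a `patch_side^2` patch collapses to two scalars:
#'   `"row_mean"` (mean of each row, uses all pixels) or `"first_two"`
#'   (first two entries).
#' @param epsilon Guard for zero standard deviations in [standardize()].
#' @return A validated list of class `preprocess_config`.
#' @export
preprocess_config <- function(target_side = 28L, roi_side = 14L,
                              patch_side = 2L,
                              reduction = c("row_mean", "first_two"),
                              epsilon = 1e-8) {
  reduction <- match.arg(reduction)
  if (!is_count(target_side)) stop_invalid("target_side must be a positive integer")
  if (!is_count(roi_side) || roi_side %% 2L != 0L) {
    stop_invalid("roi_side must be a positive even integer")
  }
  if (roi_side > target_side) stop_invalid("roi_side must be <= target_side")
  if (roi_side %% patch_side != 0L) {
    stop_invalid("roi_side must be divisible by patch_side")
  }
  if (!is.numeric(epsilon) || epsilon <= 0) stop_invalid("epsilon must be > 0")
  structure(list(target_side = as.integer(target_side),
                 roi_side = as.integer(roi_side),
                 patch_side = as.integer(patch_side),
                 reduction = reduction, epsilon = epsilon),
            class = "preprocess_config")
}

#' Standardize an image
#'
#' Applies \eqn{X' = (X - \mu) / \sigma} per pixel, guarding
#' \eqn{\sigma} by `epsilon` so constant images map to zero rather than
#' dividing by zero.
#'
#' @param image Numeric matrix.
#' @param mu,sigma Statistics to standardize against; default to the
#'   image's own mean and population standard deviation.
#' @param epsilon Lower bound applied to `sigma`.
#' @return A list of class `standardized_image` with `pixels`, `mu`, `sigma`.
#' @export
standardize <- function(image, mu = mean(image),
                        sigma = stats::sd(as.numeric(image)) *
                          sqrt((length(image) - 1) / length(image)),
                        epsilon = 1e-8) {
  if (!is.numeric(sigma) || sigma < 0) stop_invalid("sigma must be >= 0")
  s <- max(sigma, epsilon)
  structure(list(pixels = (image - mu) / s, mu = mu, sigma = s),
            class = "standardized_image")
}

#' Undo a standardization
#'
#' @param std A `standardized_image`.
#' @return The original pixel matrix.
#' @export
unstandardize <- function(std) {
  std$pixels * std$sigma + std$mu
}

#' Centered crop
#'
#' Extracts the `roi_side x roi_side` block whose 0-based top-left corner is
#' `(floor((H - roi)/2), floor((W - roi)/2))`.
#'
#' @param image Numeric matrix.
#' @param roi_side Crop side; must not exceed either image dimension.
#' @return The cropped matrix.
#' @export
center_crop <- function(image, roi_side) {
  h <- nrow(image); w <- ncol(image)
  if (roi_side > h || roi_side > w) {
    stop_invalid("roi_side %d exceeds image size %dx%d", roi_side, h, w)
  }
  r0 <- (h - roi_side) %/% 2L
  c0 <- (w - roi_side) %/% 2L
  image[(r0 + 1L):(r0 + roi_side), (c0 + 1L):(c0 + roi_side), drop = FALSE]
}

#' Extract non-overlapping square patches
#'
#' Tiles the ROI with `patch_side x patch_side` blocks at stride
#' `patch_side`, returned in row-major order of the patch grid.
#'
#' @param roi Square numeric matrix whose side is divisible by `patch_side`.
#' @param patch_side Patch side.
#' @return List of patch matrices, with attributes `grid_rows`/`grid_cols`.
#' @export
extract_patches <- function(roi, patch_side = 2L) {
  side <- nrow(roi)
  if (ncol(roi) != side) stop_invalid("roi must be square")
  if (side %% patch_side != 0L) {
    stop_invalid("roi side %d not divisible by patch_side %d", side, patch_side)
  }
  g <- side %/% patch_side
  patches <- vector("list", g * g)
  k <- 0L
  for (i in seq_len(g)) {
    for (j in seq_len(g)) {
      k <- k + 1L
      rows <- ((i - 1L) * patch_side + 1L):(i * patch_side)
      cols <- ((j - 1L) * patch_side + 1L):(j * patch_side)
      patches[[k]] <- roi[rows, cols, drop = FALSE]
    }
  }
  attr(patches, "grid_rows") <- g
  attr(patches, "grid_cols") <- g
  patches
}

#' Reassemble patches into the original ROI
#'
#' Inverse of [extract_patches()]; tiling is a bijection, so this
#' reproduces the ROI exactly.
#'
#' @param patches List produced by [extract_patches()].
#' @return The reassembled matrix.
#' @export
reassemble_patches <- function(patches) {
  g <- attr(patches, "grid_rows")
  p <- nrow(patches[[1L]])
  out <- matrix(0, g * p, g * p)
  k <- 0L
  for (i in seq_len(g)) {
    for (j in seq_len(g)) {
      k <- k + 1L
      out[((i - 1L) * p + 1L):(i * p), ((j - 1L) * p + 1L):(j * p)] <- patches[[k]]
    }
  }
  out
}

#' Reduce a 2x2 patch to two scalars
#'
#' `row_mean` returns the mean of each row, `((a+b)/2, (c+d)/2)` for the
#' patch `((a, b), (c, d))`; `first_two` returns the first row `(a, b)`.
#'
#' @param patch A 2x2 numeric matrix.
#' @param mode Reduction mode.
#' @return Numeric vector of length 2.
#' @export
reduce_patch <- function(patch, mode = c("row_mean", "first_two")) {
  mode <- match.arg(mode)
  if (!identical(dim(patch), c(2L, 2L))) {
    stop_invalid("patch must be 2x2, got %s", paste(dim(patch), collapse = "x"))
  }
  if (mode == "row_mean") rowMeans(patch) else c(patch[1, 1], patch[1, 2])
}

#' Bilinear resize
#'
#' Resizes a grayscale matrix with bilinear interpolation and half-pixel
#' centered sampling.
#'
#' @param image Numeric matrix.
#' @param side Output side (square output).
#' @return `side x side` numeric matrix.
#' @export
resize_bilinear <- function(image, side) {
  h <- nrow(image); w <- ncol(image)
  if (h == side && w == side) return(image)
  # half-pixel-centre sampling: source pixel k has centre k - 0.5
  ys <- (seq_len(side) - 0.5) * h / side
  xs <- (seq_len(side) - 0.5) * w / side
  i0 <- pmin(pmax(floor(ys - 0.5) + 1L, 1L), h); i1 <- pmin(i0 + 1L, h)
  j0 <- pmin(pmax(floor(xs - 0.5) + 1L, 1L), w); j1 <- pmin(j0 + 1L, w)
  fy <- pmin(pmax(ys - (i0 - 0.5), 0), 1)
  fx <- pmin(pmax(xs - (j0 - 0.5), 0), 1)
  a <- image[i0, j0, drop = FALSE]; b <- image[i0, j1, drop = FALSE]
  cc <- image[i1, j0, drop = FALSE]; d <- image[i1, j1, drop = FALSE]
  wy <- matrix(fy, side, side); wx <- matrix(fx, side, side, byrow = TRUE)
  (1 - wy) * ((1 - wx) * a + wx * b) + wy * ((1 - wx) * cc + wx * d)
}

#' Convert an RGB array to grayscale
#'
#' @param image `H x W x 3` numeric array; a matrix passes through.
#' @return Numeric matrix (channel average luminance).
#' @export
rgb_to_gray <- function(image) {
  if (is.matrix(image)) return(image)
  if (length(dim(image)) == 3L) return(apply(image, c(1, 2), mean))
  stop_invalid("image must be a matrix or H x W x C array")
}

# Full deterministic path from a [0,1] image to the [0,1] ROI that feeds
# the angle encoder: resize to target_side, then centered crop.
preprocess_roi <- function(image, config) {
  img <- rgb_to_gray(image)
  img <- resize_bilinear(img, config$target_side)
  center_crop(img, config$roi_side)
}
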