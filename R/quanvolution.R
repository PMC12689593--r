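# Quantum convolution: each 2x2 ROI patch is reduced to two values, the
# values are encoded as RY rotation angles on a 2-qubit register, the
# entangling circuit runs, and both qubits' Pauli-Z expectations become
# the two output channels at that patch's grid position.

#' Encode patch values as rotation angles
#'
#' Maps values in `[0, 1]` to angles `scale * value`. The default scale of
#' \eqn{\pi} keeps the encoding injective on `[0, 1]` (RY expectations are
#' \eqn{\cos\theta}-periodic over \eqn{2\pi}). Out-of-range values are
#' clipped with a warning.
#'
#' @param values Numeric vector of patch values, expected in `[0, 1]`.
#' @param scale Angle scale in radians (default `pi`).
#' @return Angles in radians.
#' @export
encode_angles <- function(values, scale = pi) {
  if (any(values < 0 | values > 1)) {
    warning("encode_angles: values outside [0, 1] clipped", call. = FALSE)
    values <- pmin(pmax(values, 0), 1)
  }
  scale * values
}

#' Run one patch through the quantum circuit
#'
#' Builds the circuit `[RY(pi v0) on qubit 0, RY(pi v1) on qubit 1]`
#' followed by the entangling block of `pqc`, and returns both qubits'
#' Pauli-Z expectations. With zero entangling layers this reduces to the
#' closed form `(cos(pi v0), cos(pi v1))`.
#'
#' @param values Two reduced patch values in `[0, 1]`.
#' @param pqc A [pqc_params()] object with `n_qubits = 2`.
#' @param scale Angle scale passed to [encode_angles()].
#' @return Numeric vector `(⟨Z0⟩, ⟨Z1⟩)`, entries in `[-1, 1]`.
#' @export
quanv_patch <- function(values, pqc = pqc_params(), scale = pi) {
  angles <- encode_angles(values, scale)
  gates <- c(list(gate_ry(angles[1L], 0L), gate_ry(angles[2L], 1L)),
             build_pqc(pqc))
  st <- run_circuit(gates, pqc$n_qubits)
  c(expect_z(st, 0L), expect_z(st, 1L))
}

# Vectorized fast path: for a fixed entangling block with unitary U, the
# post-encoding state of patch (v0, v1) is the real product state
# (c0 c1, c0 s1, s0 c1, s0 s1) with c = cos(pi v / 2), s = sin(pi v / 2);
# expectations follow from |U psi|^2. Identical (to rounding) to the
# gate-by-gate path, checked by tests.
quanv_patches_fast <- function(v0, v1, pqc, scale = pi) {
  a0 <- encode_angles(v0, scale) / 2
  a1 <- encode_angles(v1, scale) / 2
  psi <- rbind(cos(a0) * cos(a1), cos(a0) * sin(a1),
               sin(a0) * cos(a1), sin(a0) * sin(a1))
  if (pqc$n_layers > 0L) {
    U <- circuit_unitary(build_pqc(pqc), 2L)
    psi <- U %*% psi
  }
  p <- Mod(psi)^2
  # qubit 0 = MSB: sign pattern (+,+,-,-); qubit 1: (+,-,+,-)
  rbind(z0 = p[1L, ] + p[2L, ] - p[3L, ] - p[4L, ],
        z1 = p[1L, ] - p[2L, ] + p[3L, ] - p[4L, ])
}

#' Quanvolve a region of interest
#'
#' Tiles the ROI with non-overlapping 2x2 patches, reduces each to two
#' values, runs each through the 2-qubit circuit, and assembles the
#' `(side/2, side/2, 2)` quantum feature map: patch `(i, j)` maps to
#' output position `(i, j)`; channel `c` holds qubit `c`'s expectation.
#'
#' @param roi Square numeric matrix with values in `[0, 1]`, even side.
#' @param pqc A [pqc_params()] object.
#' @param reduction Patch reduction mode, see [reduce_patch()].
#' @return A `quantum_feature_map`: numeric array `(g, g, 2)` with entries
#'   in `[-1, 1]` and attributes `pqc_seed`, `reduction`.
#' @export
quanvolve <- function(roi, pqc = pqc_params(),
                      reduction = c("row_mean", "first_two")) {
  reduction <- match.arg(reduction)
  side <- nrow(roi)
  if (ncol(roi) != side || side %% 2L != 0L) {
    stop_invalid("roi must be square with an even side, got %dx%d",
                 nrow(roi), ncol(roi))
  }
  g <- side %/% 2L
  patches <- extract_patches(roi, 2L)
  red <- vapply(patches, reduce_patch, numeric(2L), mode = reduction)
  z <- quanv_patches_fast(red[1L, ], red[2L, ], pqc)
  out <- array(0, dim = c(g, g, 2L))
  # patches are in row-major grid order
  out[, , 1L] <- matrix(z[1L, ], g, g, byrow = TRUE)
  out[, , 2L] <- matrix(z[2L, ], g, g, byrow = TRUE)
  structure(out, class = "quantum_feature_map", pqc_seed = pqc$seed,
            reduction = reduction)
}

#' Quanvolve a whole dataset, with optional caching
#'
#' Preprocesses every image (resize to `config$target_side`, centered
#' `config$roi_side` crop of the `[0, 1]` image) and computes its quantum
#' feature map. When `cache_path` is given, results are stored together
#' with a hash of the quanvolution configuration; a later call with a
#' different configuration fails rather than silently serving stale maps.
#' Caching is refused for trainable circuits, whose angles change during
#' training.
#'
#' @param dataset A `labeled_dataset`.
#' @param pqc A [pqc_params()] object.
#' @param config A [preprocess_config()].
#' @param cache_path Optional `.rds` path for the feature-map archive.
#' @return List of class `feature_map_archive`: `maps` (`n x g x g x 2`
#'   array), `labels`, `class_names`, `meta` (pqc seed, thetas, reduction,
#'   roi_side, config hash).
#' @export
quanvolve_dataset <- function(dataset, pqc = pqc_params(),
                              config = preprocess_config(),
                              cache_path = NULL) {
  meta <- list(pqc_seed = pqc$seed, n_layers = pqc$n_layers,
               thetas = pqc$thetas, reduction = config$reduction,
               roi_side = config$roi_side, target_side = config$target_side)
  meta$config_hash <- object_hash(meta)
  if (!is.null(cache_path) && pqc$trainable) {
    stop_invalid("feature-map caching is disabled for trainable circuits")
  }
  if (!is.null(cache_path) && file.exists(cache_path)) {
    cached <- readRDS(cache_path)
    if (!identical(cached$meta$config_hash, meta$config_hash)) {
      stop_invalid(paste0(
        "stale feature-map cache: archive hash %s does not match ",
        "requested configuration hash %s"),
        cached$meta$config_hash, meta$config_hash)
    }
    return(cached)
  }
  n <- dim(dataset$images)[1L]
  g <- config$roi_side %/% 2L
  maps <- array(0, dim = c(n, g, g, 2L))
  for (i in seq_len(n)) {
    roi <- preprocess_roi(dataset$images[i, , ], config)
    maps[i, , , ] <- quanvolve(roi, pqc, reduction = config$reduction)
  }
  archive <- structure(list(maps = maps, labels = dataset$labels,
                            class_names = dataset$class_names, meta = meta),
                       class = "feature_map_archive")
  if (!is.null(cache_path)) saveRDS(archive, cache_path, compress = "gzip")
  archive
}

#' @export
print.feature_map_archive <- function(x, ...) {
  d <- dim(x$maps)
  cat(sprintf("<feature_map_archive: %d maps of %dx%dx%d, range [%.3f, %.3f]>\n",
              d[1L], d[2L], d[3L], d[4L], min(x$maps), max(x$maps)))
  cat(sprintf("  pqc seed %d, %d layer(s), reduction '%s', hash %s\n",
              x$meta$pqc_seed, x$meta$n_layers, x$meta$reduction,
              x$meta$config_hash))
  invisible(x)
}
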