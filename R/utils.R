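#' @keywords internal
"_PACKAGE"

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Fingerprint of an R object's canonical serialization, as a hex string.
# Three position-weighted byte sums (exact in doubles) are folded into a
# 32-bit value. Detects configuration / weight changes; not cryptographic.
object_hash <- function(x) {
  b <- as.numeric(serialize(x, connection = NULL, version = 2, xdr = TRUE))
  i <- seq_along(b)
  s1 <- sum(b * ((i %% 8191) + 1)) %% 4294967296
  s2 <- sum(b * ((i %% 7873) + 1)) %% 4294967296
  s3 <- sum(b * ((i %% 127) + 1)) %% 4294967296
  h <- (s1 + s2 * 3 + s3 * 7 + length(b)) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= min
}

# One-hot encode 0-based integer labels into an n x K matrix.
one_hot <- function(labels, n_classes) {
  y <- matrix(0, nrow = length(labels), ncol = n_classes)
  y[cbind(seq_along(labels), labels + 1L)] <- 1
  y
}
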