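# Dense statevector simulation for small qubit registers.
#
# Convention: qubit 0 is the MOST significant bit of the basis index, so for
# a 2-qubit register the amplitude vector is ordered |00>, |01>, |10>, |11>
# with qubit 0 the left bit. All qubit indices are 0-based.

#' Initialize a qubit register in the all-zeros state
#'
#' Returns a statevector object for `n_qubits` qubits with amplitude 1 on
#' the basis state \eqn{|0...0\rangle}.
#'
#' @param n_qubits Number of qubits (integer >= 1).
#' @return An object of class `qstate`: a list with complex `amplitudes`
#'   (length `2^n_qubits`) and `n_qubits`.
#' @examples
#' s <- qstate_init(2)
#' s$amplitudes  # (1, 0, 0, 0)
#' @export
qstate_init <- function(n_qubits) {
  if (!is_count(n_qubits, min = 1L)) {
    stop_invalid("n_qubits must be an integer >= 1, got %s", format(n_qubits))
  }
  amp <- complex(real = numeric(2^n_qubits))
  amp[1] <- 1 + 0i
  structure(list(amplitudes = amp, n_qubits = as.integer(n_qubits)),
            class = "qstate")
}

check_qubit <- function(state, qubit, what = "qubit") {
  if (!is_count(qubit, min = 0L) || qubit >= state$n_qubits) {
    stop_invalid("%s index %s out of range for %d-qubit register",
                 what, format(qubit), state$n_qubits)
  }
}

# Stride between paired basis indices that differ only in `qubit`'s bit.
qubit_stride <- function(n_qubits, qubit) 2^(n_qubits - 1L - qubit)

# 0-based basis indices whose `qubit` bit is 0.
bit0_indices <- function(n_qubits, qubit) {
  idx <- 0:(2^n_qubits - 1L)
  idx[bitwAnd(idx %/% qubit_stride(n_qubits, qubit), 1L) == 0L]
}

#' Apply an RY rotation to one qubit
#'
#' The single-qubit rotation about the Y axis,
#' \deqn{RY(\theta) = \begin{pmatrix} \cos\theta/2 & -\sin\theta/2 \\
#'   \sin\theta/2 & \cos\theta/2 \end{pmatrix},}
#' applied to the indexed qubit of a statevector. Norm is preserved.
#'
#' @param state A `qstate`.
#' @param theta Rotation angle in radians.
#' @param qubit 0-based qubit index.
#' @return The rotated `qstate`.
#' @export
apply_ry <- function(state, theta, qubit) {
  check_qubit(state, qubit)
  c2 <- cos(theta / 2); s2 <- sin(theta / 2)
  i0 <- bit0_indices(state$n_qubits, qubit) + 1L
  i1 <- i0 + qubit_stride(state$n_qubits, qubit)
  a0 <- state$amplitudes[i0]; a1 <- state$amplitudes[i1]
  state$amplitudes[i0] <- c2 * a0 - s2 * a1
  state$amplitudes[i1] <- s2 * a0 + c2 * a1
  state
}

#' Apply a CNOT gate
#'
#' Flips the target qubit on basis states where the control qubit is 1:
#' \eqn{|q_c, q_t\rangle \to |q_c, q_c \oplus q_t\rangle}.
#'
#' @param state A `qstate`.
#' @param control,target Distinct 0-based qubit indices.
#' @return The transformed `qstate`.
#' @export
apply_cnot <- function(state, control, target) {
  check_qubit(state, control, "control")
  check_qubit(state, target, "target")
  if (control == target) stop_invalid("control and target must differ")
  n <- state$n_qubits
  idx <- 0:(2^n - 1L)
  cbit <- bitwAnd(idx %/% qubit_stride(n, control), 1L)
  tbit <- bitwAnd(idx %/% qubit_stride(n, target), 1L)
  src <- idx[cbit == 1L & tbit == 0L]
  dst <- src + qubit_stride(n, target)
  a <- state$amplitudes
  state$amplitudes[src + 1L] <- a[dst + 1L]
  state$amplitudes[dst + 1L] <- a[src + 1L]
  state
}

#' Gate constructors
#'
#' Build gate descriptions consumed by [run_circuit()].
#'
#' @param theta Rotation angle in radians (RY).
#' @param target 0-based target qubit index.
#' @param control 0-based control qubit index (CNOT).
#' @return A list describing the gate, of class `gate_op`.
#' @export
gate_ry <- function(theta, target) {
  structure(list(kind = "RY", angle = theta, target = as.integer(target)),
            class = "gate_op")
}

#' @rdname gate_ry
#' @export
gate_cnot <- function(control, target) {
  if (control == target) stop_invalid("control and target must differ")
  structure(list(kind = "CNOT", control = as.integer(control),
                 target = as.integer(target)),
            class = "gate_op")
}

#' Run a gate sequence on the all-zeros state
#'
#' @param gates List of `gate_op` objects, applied left to right.
#' @param n_qubits Register size.
#' @param state Optional starting `qstate`; defaults to `qstate_init(n_qubits)`.
#' @return Final `qstate`.
#' @export
run_circuit <- function(gates, n_qubits, state = NULL) {
  if (is.null(state)) state <- qstate_init(n_qubits)
  for (g in gates) {
    state <- switch(g$kind,
      RY   = apply_ry(state, g$angle, g$target),
      CNOT = apply_cnot(state, g$control, g$target),
      stop_invalid("unknown gate kind '%s'", g$kind)
    )
  }
  state
}

#' Pauli-Z expectation of one qubit
#'
#' Computes \eqn{\langle\psi|Z_j|\psi\rangle = \sum_b (\pm 1)\,|a_b|^2},
#' with sign +1 when the qubit's bit in the basis index is 0 and -1 when it
#' is 1. Always lies in \eqn{[-1, 1]}.
#'
#' @param state A `qstate`.
#' @param qubit 0-based qubit index.
#' @return Real expectation value in `[-1, 1]`.
#' @export
expect_z <- function(state, qubit) {
  check_qubit(state, qubit)
  idx <- 0:(2^state$n_qubits - 1L)
  signs <- 1 - 2 * bitwAnd(idx %/% qubit_stride(state$n_qubits, qubit), 1L)
  sum(signs * Mod(state$amplitudes)^2)
}

#' Parameterized entangling-circuit parameters
#'
#' Describes the trainable block applied after angle encoding: per layer,
#' an RY rotation on every qubit followed by a linear CNOT chain. Angles
#' default to uniform draws on \eqn{[0, 2\pi)} from `seed`, the standard
#' "random layers" initialization for quanvolution.
#'
#' @param n_qubits Register size (default 2).
#' @param n_layers Number of entangling layers (integer >= 0, default 2).
#' @param thetas Optional `n_layers x n_qubits` angle matrix; drawn from
#'   `seed` when `NULL`.
#' @param seed Integer seed for the angle draw.
#' @param trainable Logical; when `TRUE` the angles are meant to be updated
#'   by parameter-shift gradients and feature maps must not be cached.
#' @return An object of class `pqc_params`.
#' @export
pqc_params <- function(n_qubits = 2L, n_layers = 2L, thetas = NULL,
                       seed = 1L, trainable = FALSE) {
  if (!is_count(n_qubits, 1L)) stop_invalid("n_qubits must be >= 1")
  if (!is_count(n_layers, 0L)) stop_invalid("n_layers must be >= 0")
  if (is.null(thetas)) {
    thetas <- with_seed(seed, matrix(stats::runif(n_layers * n_qubits, 0, 2 * pi),
                                     nrow = n_layers, ncol = n_qubits))
  } else {
    thetas <- matrix(as.numeric(thetas), nrow = n_layers, ncol = n_qubits)
  }
  if (!identical(dim(thetas), c(as.integer(n_layers), as.integer(n_qubits)))) {
    stop_invalid("thetas must be an n_layers x n_qubits matrix")
  }
  structure(list(n_qubits = as.integer(n_qubits),
                 n_layers = as.integer(n_layers),
                 thetas = thetas, seed = as.integer(seed),
                 trainable = isTRUE(trainable)),
            class = "pqc_params")
}

#' Build the entangling-circuit gate list
#'
#' Per layer: `RY(theta[l, q])` on every qubit `q`, then CNOTs
#' `q -> q + 1` down the chain (a single CNOT 0 -> 1 for 2 qubits).
#'
#' @param params A `pqc_params` object.
#' @param thetas Optional angle matrix overriding `params$thetas` (used by
#'   the parameter-shift rule).
#' @return List of `gate_op`.
#' @export
build_pqc <- function(params, thetas = NULL) {
  if (is.null(thetas)) thetas <- params$thetas
  gates <- list()
  if (params$n_layers == 0L) return(gates)
  for (l in seq_len(params$n_layers)) {
    for (q in seq_len(params$n_qubits) - 1L) {
      gates[[length(gates) + 1L]] <- gate_ry(thetas[l, q + 1L], q)
    }
    if (params$n_qubits >= 2L) {
      for (q in seq_len(params$n_qubits - 1L) - 1L) {
        gates[[length(gates) + 1L]] <- gate_cnot(q, q + 1L)
      }
    }
  }
  gates
}

#' Dense unitary of a gate sequence
#'
#' Materializes the `2^n x 2^n` matrix of a circuit by running it on every
#' basis state. Used to apply a fixed circuit to many encoded states at
#' once.
#'
#' @param gates List of `gate_op`.
#' @param n_qubits Register size.
#' @return Complex matrix.
#' @export
circuit_unitary <- function(gates, n_qubits) {
  d <- 2^n_qubits
  U <- matrix(0 + 0i, d, d)
  for (j in seq_len(d)) {
    s <- qstate_init(n_qubits)
    s$amplitudes[] <- 0 + 0i
    s$amplitudes[j] <- 1 + 0i
    U[, j] <- run_circuit(gates, n_qubits, state = s)$amplitudes
  }
  U
}

#' Parameter-shift gradient of a Pauli-Z expectation
#'
#' For an expectation \eqn{f(\theta)} produced by an RY angle, the exact
#' gradient is \eqn{[f(\theta + \pi/2) - f(\theta - \pi/2)] / 2}.
#'
#' @param circuit_builder Function `(thetas) -> gate list` mapping an angle
#'   matrix to a full circuit; defaults to [build_pqc()] on `params`.
#' @param params A `pqc_params` object holding the current angles.
#' @param observable_qubit 0-based qubit whose Z expectation is
#'   differentiated.
#' @param theta_index Either a linear (column-major) index into the angle
#'   matrix or a `(layer, qubit)` pair of 1-based positions.
#' @return The scalar gradient.
#' @export
parameter_shift_grad <- function(circuit_builder = NULL, params,
                                 observable_qubit, theta_index) {
  if (is.null(circuit_builder)) {
    circuit_builder <- function(thetas) build_pqc(params, thetas = thetas)
  }
  th <- params$thetas
  if (length(theta_index) == 2L) {
    theta_index <- theta_index[1L] + (theta_index[2L] - 1L) * nrow(th)
  }
  if (!is_count(theta_index, 1L) || theta_index > length(th)) {
    stop_invalid("theta_index out of range")
  }
  f <- function(shift) {
    th2 <- th
    th2[theta_index] <- th2[theta_index] + shift
    expect_z(run_circuit(circuit_builder(th2), params$n_qubits),
             observable_qubit)
  }
  (f(pi / 2) - f(-pi / 2)) / 2
}

#' Serialize / restore entangling-circuit parameters
#'
#' Round-trips a `pqc_params` object through YAML so a feature-map archive
#' can be reproduced exactly.
#'
#' @param params A `pqc_params` object.
#' @param path File path.
#' @return `read_pqc_params` returns the restored `pqc_params`.
#' @export
write_pqc_params <- function(params, path) {
  yaml::write_yaml(list(
    n_qubits = params$n_qubits, n_layers = params$n_layers,
    seed = params$seed, trainable = params$trainable,
    thetas = as.numeric(params$thetas)
  ), path)
  invisible(path)
}

#' @rdname write_pqc_params
#' @export
read_pqc_params <- function(path) {
  y <- yaml::read_yaml(path)
  pqc_params(n_qubits = y$n_qubits, n_layers = y$n_layers,
             thetas = matrix(y$thetas, nrow = y$n_layers, ncol = y$n_qubits),
             seed = y$seed, trainable = y$trainable)
}

#' @export
print.qstate <- function(x, ...) {
  cat(sprintf("<qstate: %d qubit(s)>\n", x$n_qubits))
  basis <- vapply(0:(2^x$n_qubits - 1L), function(b) {
    paste(rev(as.integer(intToBits(b))[seq_len(x$n_qubits)]), collapse = "")
  }, character(1))
  for (i in seq_along(x$amplitudes)) {
    cat(sprintf("  |%s>  %s\n", basis[i], format(x$amplitudes[i], digits = 4)))
  }
  invisible(x)
}
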