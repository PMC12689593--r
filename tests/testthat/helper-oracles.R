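# Independent dense-matrix oracle for the statevector simulator: every
# gate is expanded to its full 2^n x 2^n matrix via explicit Kronecker
# products (qubit 0 = most significant bit = leftmost factor), and the
# circuit is the left-to-right matrix product applied to e1.

ry_matrix <- function(theta) {
  matrix(c(cos(theta / 2), sin(theta / 2),
           -sin(theta / 2), cos(theta / 2)), 2, 2)
}

oracle_gate_matrix <- function(gate, n_qubits) {
  if (gate$kind == "RY") {
    m <- matrix(1, 1, 1)
    for (q in seq_len(n_qubits) - 1L) {
      m <- kronecker(m, if (q == gate$target) ry_matrix(gate$angle) else diag(2))
    }
    m
  } else {
    d <- 2^n_qubits
    m <- matrix(0, d, d)
    for (b in 0:(d - 1L)) {
      cbit <- bitwAnd(b %/% 2^(n_qubits - 1L - gate$control), 1L)
      out <- if (cbit == 1L) bitwXor(b, 2^(n_qubits - 1L - gate$target)) else b
      m[out + 1L, b + 1L] <- 1
    }
    m
  }
}

oracle_run <- function(gates, n_qubits) {
  psi <- numeric(2^n_qubits); psi[1] <- 1
  for (g in gates) psi <- oracle_gate_matrix(g, n_qubits) %*% psi
  as.numeric(psi)
}

random_circuit <- function(n_qubits, n_gates) {
  lapply(seq_len(n_gates), function(i) {
    if (n_qubits >= 2 && stats::runif(1) < 0.3) {
      qs <- sample(n_qubits, 2) - 1L
      gate_cnot(qs[1], qs[2])
    } else {
      gate_ry(stats::runif(1, 0, 2 * pi), sample(n_qubits, 1) - 1L)
    }
  })
}

# Shared small fixtures
tiny_phantoms <- function(n = 60, noise_sd = 0.05, seed = 7) {
  generate_phantoms(phantom_spec(noise_sd = noise_sd, seed = seed), n)
}
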