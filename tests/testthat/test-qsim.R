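test_that("initial states are |0...0> with unit norm", {
  expect_equal(qstate_init(2)$amplitudes, c(1, 0, 0, 0) + 0i)
  expect_equal(qstate_init(1)$amplitudes, c(1, 0) + 0i)
  expect_equal(sum(Mod(qstate_init(3)$amplitudes)^2), 1)
  expect_error(qstate_init(0), "n_qubits")
})

test_that("RY rotations match the matrix definition", {
  s <- qstate_init(1)
  expect_equal(apply_ry(s, 0, 0)$amplitudes, s$amplitudes)
  expect_equal(Re(apply_ry(s, pi, 0)$amplitudes), c(0, 1), tolerance = 1e-12)
  expect_equal(Re(apply_ry(s, pi / 2, 0)$amplitudes),
               c(sqrt(2) / 2, sqrt(2) / 2), tolerance = 1e-12)
  expect_error(apply_ry(s, 1, 1), "out of range")
})

test_that("CNOT maps |q1,q2> to |q1, q1 xor q2>", {
  s00 <- qstate_init(2)
  expect_equal(apply_cnot(s00, 0, 1)$amplitudes, s00$amplitudes)
  # |10> (index 2 under qubit-0-as-MSB) -> |11>
  s10 <- qstate_init(2); s10$amplitudes <- c(0, 0, 1, 0) + 0i
  expect_equal(apply_cnot(s10, 0, 1)$amplitudes, c(0, 0, 0, 1) + 0i)
  # involution
  expect_equal(apply_cnot(apply_cnot(s10, 0, 1), 0, 1)$amplitudes,
               s10$amplitudes)
  expect_error(apply_cnot(s00, 1, 1), "differ")
})

test_that("run_circuit composes gates left to right", {
  expect_equal(run_circuit(list(), 2)$amplitudes, c(1, 0, 0, 0) + 0i)
  s <- run_circuit(list(gate_ry(pi, 0), gate_cnot(0, 1)), 2)
  expect_equal(Re(s$amplitudes), c(0, 0, 0, 1), tolerance = 1e-12)
})

test_that("simulator matches the dense Kronecker-product oracle", {
  set.seed(1234)
  for (i in 1:60) {
    n <- sample(1:3, 1)
    gates <- random_circuit(n, sample(1:30, 1))
    psi <- run_circuit(gates, n)$amplitudes
    expect_lt(max(abs(Re(psi) - oracle_run(gates, n))), 1e-10)
    expect_lt(max(abs(Im(psi))), 1e-10)  # RY/CNOT circuits stay real
    expect_lt(abs(sum(Mod(psi)^2) - 1), 1e-10)
  }
})

test_that("Pauli-Z expectation follows the closed form and bounds", {
  s00 <- qstate_init(2)
  expect_equal(expect_z(s00, 0), 1)
  expect_equal(expect_z(s00, 1), 1)
  s11 <- run_circuit(list(gate_ry(pi, 0), gate_ry(pi, 1)), 2)
  expect_equal(expect_z(s11, 0), -1, tolerance = 1e-12)
  expect_equal(expect_z(s11, 1), -1, tolerance = 1e-12)
  for (theta in seq(0, 2 * pi, length.out = 100)) {
    z <- expect_z(apply_ry(qstate_init(1), theta, 0), 0)
    expect_equal(z, cos(theta), tolerance = 1e-12)
    expect_true(z >= -1 - 1e-12 && z <= 1 + 1e-12)
  }
})

test_that("gate applications preserve the norm and invert cleanly", {
  set.seed(99)
  for (i in 1:20) {
    n <- sample(2:3, 1)
    s <- run_circuit(random_circuit(n, 15), n)
    expect_lt(abs(sqrt(sum(Mod(s$amplitudes)^2)) - 1), 1e-10)
    theta <- stats::runif(1, 0, 2 * pi)
    q <- sample(n, 1) - 1L
    back <- apply_ry(apply_ry(s, theta, q), -theta, q)
    expect_lt(max(Mod(back$amplitudes - s$amplitudes)), 1e-12)
  }
})

test_that("the entangling block has the documented layout and seeding", {
  expect_length(build_pqc(pqc_params(n_layers = 0)), 0)
  gates <- build_pqc(pqc_params(n_qubits = 2, n_layers = 1, seed = 5))
  expect_length(gates, 3)  # 2 RY + 1 CNOT
  expect_equal(vapply(gates, `[[`, "", "kind"), c("RY", "RY", "CNOT"))
  p1 <- pqc_params(n_layers = 2, seed = 11)
  p2 <- pqc_params(n_layers = 2, seed = 11)
  expect_identical(p1$thetas, p2$thetas)
  expect_true(all(p1$thetas >= 0 & p1$thetas < 2 * pi))
  # 3-qubit chain: 3 RY + 2 CNOT per layer
  expect_length(build_pqc(pqc_params(n_qubits = 3, n_layers = 2)), 10)
})

test_that("parameter-shift gradients are exact", {
  # single RY on |0>: f = cos(theta), gradient -sin(theta)
  for (theta in seq(0, 2 * pi, length.out = 50)) {
    p <- pqc_params(n_qubits = 1, n_layers = 1,
                    thetas = matrix(theta, 1, 1))
    g <- parameter_shift_grad(params = p, observable_qubit = 0,
                              theta_index = 1)
    expect_equal(g, -sin(theta), tolerance = 1e-10)
  }
  # gradient vanishes at the maximum of f
  p0 <- pqc_params(n_qubits = 1, n_layers = 1, thetas = matrix(0, 1, 1))
  expect_equal(parameter_shift_grad(params = p0, observable_qubit = 0,
                                    theta_index = 1), 0, tolerance = 1e-12)
  # central finite differences on random 2-qubit circuits
  set.seed(7)
  for (i in 1:10) {
    p <- pqc_params(n_layers = sample(1:3, 1), seed = i)
    idx <- sample(length(p$thetas), 1)
    q <- sample(2, 1) - 1L
    g <- parameter_shift_grad(params = p, observable_qubit = q,
                              theta_index = idx)
    h <- 1e-5
    f <- function(d) {
      th <- p$thetas; th[idx] <- th[idx] + d
      expect_z(run_circuit(build_pqc(p, thetas = th), 2), q)
    }
    expect_equal(g, (f(h) - f(-h)) / (2 * h), tolerance = 1e-6)
  }
  expect_error(parameter_shift_grad(params = pqc_params(n_layers = 1),
                                    observable_qubit = 0, theta_index = 9),
               "theta_index")
})

test_that("entangling parameters round-trip through YAML", {
  p <- pqc_params(n_layers = 3, seed = 42)
  f <- tempfile(fileext = ".yaml")
  write_pqc_params(p, f)
  p2 <- read_pqc_params(f)
  expect_equal(p2$thetas, p$thetas)
  expect_identical(p2$seed, p$seed)
  expect_identical(p2$n_layers, p$n_layers)
})
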