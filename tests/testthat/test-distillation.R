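test_that("temperature softening behaves at its limits", {
  z <- c(2, -1, 0.5)
  expect_equal(softened_probs(z, 1), softmax(z))
  expect_equal(softened_probs(z, 1e9), rep(1 / 3, 3), tolerance = 1e-6)
  expect_equal(softened_probs(c(2, 0), 2), softmax(c(1, 0)), tolerance = 1e-12)
  expect_equal(softened_probs(c(2, 0), 2), c(0.7311, 0.2689), tolerance = 1e-4)
  expect_error(softened_probs(z, 0), "temperature")
})

test_that("raising the temperature flattens non-uniform distributions", {
  z <- c(3, 1, 0, -2)
  temps <- c(1, 2, 5, 20, 100)
  maxp <- vapply(temps, function(Tt) max(softened_probs(z, Tt)), numeric(1))
  expect_true(all(diff(maxp) < 0))
})

test_that("KL divergence is zero at equality and nonnegative always", {
  p <- c(0.2, 0.3, 0.5)
  expect_equal(kl_divergence(p, p), 0)
  expect_equal(kl_divergence(c(1, 0), c(0.5, 0.5)), log(2))
  set.seed(11)
  for (i in 1:1000) {
    a <- softmax(stats::runif(4, -5, 5))
    b <- softmax(stats::runif(4, -5, 5))
    expect_gte(kl_divergence(a, b), 0)
  }
})

test_that("the combined loss reduces to its pure components", {
  set.seed(3)
  y <- c(1, 0, 0, 0)
  s <- stats::runif(4, -2, 2); t <- stats::runif(4, -2, 2)
  # alpha = 1: exactly cross-entropy
  expect_equal(distill_loss(y, s, t, distill_config(alpha = 1)),
               cross_entropy(y, softmax(s)))
  # alpha = 0: exactly the KL term
  expect_equal(distill_loss(y, s, t, distill_config(temperature = 5, alpha = 0)),
               kl_divergence(softened_probs(t, 5), softened_probs(s, 5)))
  # identical logits: KL term vanishes
  expect_equal(distill_loss(y, s, s, distill_config(alpha = 0.3)),
               0.3 * cross_entropy(y, softmax(s)))
  # continuity/linearity in alpha
  l0 <- distill_loss(y, s, t, distill_config(alpha = 0))
  l1 <- distill_loss(y, s, t, distill_config(alpha = 1))
  lh <- distill_loss(y, s, t, distill_config(alpha = 0.5))
  expect_equal(lh, (l0 + l1) / 2, tolerance = 1e-12)
  expect_error(distill_loss(y, s, t[1:3], distill_config()), "shape")
})

test_that("the hand-evaluated two-term example matches", {
  y <- c(1, 0); s <- c(0, 0); tl <- c(2, 0)
  cfg <- distill_config(temperature = 2, alpha = 0.5)
  tsoft <- softened_probs(tl, 2)      # softmax((1, 0))
  expected <- 0.5 * log(2) +
    0.5 * (tsoft[1] * log(tsoft[1] / 0.5) + tsoft[2] * log(tsoft[2] / 0.5))
  expect_equal(distill_loss(y, s, tl, cfg), expected, tolerance = 1e-12)
  # T^2 rescaling multiplies only the KL term
  cfg2 <- distill_config(temperature = 2, alpha = 0.5,
                         squared_T_scaling = TRUE)
  expect_equal(distill_loss(y, s, tl, cfg2),
               0.5 * log(2) + 4 * (expected - 0.5 * log(2)),
               tolerance = 1e-12)
})

test_that("the KL gradient vanishes when student matches the teacher", {
  set.seed(6)
  tl <- stats::runif(4, -2, 2)
  cfg <- distill_config(temperature = 5, alpha = 0)
  y <- c(0, 0, 1, 0)
  h <- 1e-6
  for (j in 1:4) {
    sp <- tl; sp[j] <- sp[j] + h
    sm <- tl; sm[j] <- sm[j] - h
    num <- (distill_loss(y, sp, tl, cfg) - distill_loss(y, sm, tl, cfg)) / (2 * h)
    expect_lt(abs(num), 1e-6)
  }
})

test_that("distillation freezes the teacher and trains the student", {
  d <- tiny_phantoms(80, noise_sd = 0.03, seed = 15)
  pre <- preprocess_config()
  arch <- quanvolve_dataset(d, pqc_params(n_layers = 1, seed = 3), pre)
  n <- dim(d$images)[1]
  tx <- array(0, c(n, 14, 14, 1))
  for (i in seq_len(n)) {
    tx[i, , , 1] <- standardize(center_crop(d$images[i, , ], 14))$pixels
  }
  tc <- train_config(max_epochs = 6)
  teacher <- qcnn_train(qcnn_spec("teacher", c(14, 14, 1), 4,
                                  conv_filters = c(8L, 16L),
                                  dense_units = 16L),
                        tx, d$labels, config = tc, seed = 21)
  sum_before <- qcnn_checksum(teacher)
  sspec <- qcnn_spec("student", c(7, 7, 2), 4, conv_filters = c(8L, 16L),
                     dense_units = 16L)
  student <- train_with_distillation(teacher, tx, sspec, arch$maps, d$labels,
                                     cfg = distill_config(),
                                     config = tc, seed = 22)
  expect_identical(qcnn_checksum(teacher), sum_before)
  expect_true(student$trained)
  h <- student$history
  expect_true(all(h$kl_component >= 0))
  expect_lt(mean(tail(h$total_loss, 2)), mean(head(h$total_loss, 2)))

  # alpha = 1 distillation reproduces the plain training trajectory
  kd1 <- train_with_distillation(teacher, tx, sspec, arch$maps, d$labels,
                                 cfg = distill_config(alpha = 1),
                                 config = tc, seed = 30)
  plain <- qcnn_train(sspec, arch$maps, d$labels, config = tc, seed = 30)
  expect_equal(kd1$weights, plain$weights, tolerance = 1e-12)
  expect_error(train_with_distillation(qcnn_init(sspec), tx, sspec,
                                       arch$maps, d$labels),
               "trained")
})

test_that("training histories export to CSV", {
  d <- tiny_phantoms(40, seed = 18)
  arch <- quanvolve_dataset(d, pqc_params(n_layers = 0), preprocess_config())
  net <- qcnn_train(qcnn_spec("student", c(7, 7, 2), 4,
                              conv_filters = c(4L, 8L), dense_units = 8L),
                    arch$maps, d$labels,
                    config = train_config(max_epochs = 3), seed = 1)
  f <- tempfile(fileext = ".csv")
  write_history_csv(net, f)
  h <- utils::read.csv(f)
  expect_equal(nrow(h), nrow(net$history))
  expect_true(all(c("total_loss", "ce_component", "kl_component") %in% names(h)))
})
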