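# Small convolutional classifiers trained by backpropagation.
#
# Architecture (both roles):
#   Conv(f1, 3x3, same) -> ReLU -> MaxPool(2x2, skipped if a spatial side
#   < 2) -> Conv(f2, 3x3, same) -> ReLU -> Flatten -> Dense(dense_units)
#   -> ReLU -> Dropout -> Dense(n_classes) -> logits.
# Softmax is applied only at the loss / inference level. The teacher role
# uses (128, 256) filters, the student (64, 128). Convolutions are
# evaluated as im2col matrix products so the heavy lifting stays in BLAS.
#
# Batches are stored as (N, H, W, C) arrays. Spatial/feature flattening
# follows R's column-major layout throughout (forward and backward agree,
# which is all that matters).

#' Model specification
#'
#' @param role `"teacher"` (Conv2D 128/256) or `"student"` (Conv2D 64/128).
#' @param input_shape Integer `(H, W, C)` of the input tensor; the student
#'   consumes quantum feature maps (default `(7, 7, 2)`), the teacher
#'   standardized images.
#' @param n_classes Number of output classes.
#' @param conv_filters Optional pair overriding the role's filter counts.
#' @param dense_units Width of the penultimate dense layer (default 64).
#' @param dropout_rate Dropout probability before the output layer
#'   (default 0.5), active only during training.
#' @return A list of class `qcnn_spec`.
#' @export
qcnn_spec <- function(role = c("student", "teacher"),
                      input_shape = c(7L, 7L, 2L), n_classes = 4L,
                      conv_filters = NULL, dense_units = 64L,
                      dropout_rate = 0.5) {
  role <- match.arg(role)
  if (is.null(conv_filters)) {
    conv_filters <- if (role == "teacher") c(128L, 256L) else c(64L, 128L)
  }
  if (length(input_shape) == 2L) input_shape <- c(input_shape, 1L)
  input_shape <- as.integer(input_shape)
  if (any(input_shape[1:2] < 3L)) {
    stop_invalid("input spatial dims must be >= the 3x3 kernel")
  }
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop_invalid("dropout_rate must lie in [0, 1)")
  }
  structure(list(role = role, input_shape = input_shape,
                 n_classes = as.integer(n_classes),
                 conv_filters = as.integer(conv_filters),
                 dense_units = as.integer(dense_units),
                 dropout_rate = dropout_rate),
            class = "qcnn_spec")
}

# ---- tensor plumbing -------------------------------------------------------

# im2col for a 3x3 'same' convolution: (N,H,W,C) -> (N*H*W, 9C), rows in
# column-major (n, i, j) order, zero padding of one pixel.
im2col3 <- function(x) {
  d <- dim(x); n <- d[1L]; h <- d[2L]; w <- d[3L]; cc <- d[4L]
  xp <- array(0, dim = c(n, h + 2L, w + 2L, cc))
  xp[, 2:(h + 1L), 2:(w + 1L), ] <- x
  out <- matrix(0, n * h * w, 9L * cc)
  k <- 0L
  for (dj in 0:2) for (di in 0:2) {
    k <- k + 1L
    blk <- xp[, di + seq_len(h), dj + seq_len(w), , drop = FALSE]
    dim(blk) <- c(n * h * w, cc)
    out[, ((k - 1L) * cc + 1L):(k * cc)] <- blk
  }
  out
}

# Adjoint of im2col3: scatter-add column gradients back onto (N,H,W,C).
col2im3 <- function(dcol, n, h, w, cc) {
  dxp <- array(0, dim = c(n, h + 2L, w + 2L, cc))
  k <- 0L
  for (dj in 0:2) for (di in 0:2) {
    k <- k + 1L
    blk <- dcol[, ((k - 1L) * cc + 1L):(k * cc), drop = FALSE]
    dim(blk) <- c(n, h, w, cc)
    dxp[, di + seq_len(h), dj + seq_len(w), ] <-
      dxp[, di + seq_len(h), dj + seq_len(w), , drop = FALSE] + blk
  }
  dxp[, 2:(h + 1L), 2:(w + 1L), , drop = FALSE]
}

# 2x2 max pooling with stride 2 (floor semantics: a trailing odd row or
# column is dropped). Returns the pooled tensor and the argmax masks
# needed by the backward pass; ties go to the first window slot.
maxpool2 <- function(x) {
  d <- dim(x); n <- d[1L]; h2 <- d[2L] %/% 2L; w2 <- d[3L] %/% 2L; cc <- d[4L]
  ri <- seq_len(h2) * 2L; ci <- seq_len(w2) * 2L
  s <- list(x[, ri - 1L, ci - 1L, , drop = FALSE],
            x[, ri - 1L, ci, , drop = FALSE],
            x[, ri, ci - 1L, , drop = FALSE],
            x[, ri, ci, , drop = FALSE])
  m <- pmax(s[[1L]], s[[2L]], s[[3L]], s[[4L]])
  masks <- vector("list", 4L)
  taken <- array(FALSE, dim = dim(m))
  for (k in 1:4) {
    masks[[k]] <- (s[[k]] == m) & !taken
    taken <- taken | masks[[k]]
  }
  list(out = m, masks = masks, in_dim = d)
}

maxpool2_backward <- function(pool, dout) {
  d <- pool$in_dim; h2 <- dim(dout)[2L]; w2 <- dim(dout)[3L]
  dx <- array(0, dim = d)
  ri <- seq_len(h2) * 2L; ci <- seq_len(w2) * 2L
  off <- list(c(-1L, -1L), c(-1L, 0L), c(0L, -1L), c(0L, 0L))
  for (k in 1:4) {
    dx[, ri + off[[k]][1L], ci + off[[k]][2L], ] <-
      dx[, ri + off[[k]][1L], ci + off[[k]][2L], , drop = FALSE] +
      dout * pool$masks[[k]]
  }
  dx
}

glorot <- function(nr, nc, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Initialize network weights
#'
#' Glorot-uniform initialization from `seed`.
#'
#' @param spec A [qcnn_spec()].
#' @param seed Integer seed.
#' @return An object of class `qcnn` (untrained).
#' @export
qcnn_init <- function(spec, seed = 1L) {
  h <- spec$input_shape[1L]; w <- spec$input_shape[2L]; cc <- spec$input_shape[3L]
  f1 <- spec$conv_filters[1L]; f2 <- spec$conv_filters[2L]
  pooled <- min(h, w) >= 2L
  h2 <- if (pooled) h %/% 2L else h
  w2 <- if (pooled) w %/% 2L else w
  flat <- h2 * w2 * f2
  weights <- with_seed(seed, list(
    W1 = glorot(9L * cc, f1, 9L * cc, 9L * f1), b1 = numeric(f1),
    W2 = glorot(9L * f1, f2, 9L * f1, 9L * f2), b2 = numeric(f2),
    Wd = glorot(flat, spec$dense_units, flat, spec$dense_units),
    bd = numeric(spec$dense_units),
    Wo = glorot(spec$dense_units, spec$n_classes, spec$dense_units,
                spec$n_classes),
    bo = numeric(spec$n_classes)
  ))
  structure(list(spec = spec, weights = weights, seed = as.integer(seed),
                 pooled = pooled, history = NULL, trained = FALSE),
            class = "qcnn")
}

# Forward pass. x: (N,H,W,C). Returns logits and, when keep_cache, the
# intermediates needed for backprop. Dropout is applied only when train
# is TRUE (inverted dropout, so evaluation needs no rescaling).
qcnn_forward <- function(net, x, train = FALSE, keep_cache = FALSE) {
  w <- net$weights; spec <- net$spec
  d <- dim(x); n <- d[1L]; h <- d[2L]; wd <- d[3L]; cc <- d[4L]
  x1 <- im2col3(x)
  a1 <- x1 %*% w$W1
  a1 <- a1 + rep(w$b1, each = nrow(a1))
  a1 <- pmax(a1, 0)
  a1t <- a1; dim(a1t) <- c(n, h, wd, spec$conv_filters[1L])
  if (net$pooled) {
    pool <- maxpool2(a1t)
    p <- pool$out
  } else {
    pool <- NULL
    p <- a1t
  }
  pd <- dim(p)
  x2 <- im2col3(p)
  a2 <- x2 %*% w$W2
  a2 <- a2 + rep(w$b2, each = nrow(a2))
  a2 <- pmax(a2, 0)
  flat <- a2; dim(flat) <- c(n, pd[2L] * pd[3L] * spec$conv_filters[2L])
  dm <- flat %*% w$Wd
  dm <- dm + rep(w$bd, each = n)
  dm <- pmax(dm, 0)
  if (train && spec$dropout_rate > 0) {
    keep <- 1 - spec$dropout_rate
    mask <- matrix(stats::runif(length(dm)) < keep, nrow(dm), ncol(dm)) / keep
    dmd <- dm * mask
  } else {
    mask <- NULL
    dmd <- dm
  }
  logits <- dmd %*% w$Wo
  logits <- logits + rep(w$bo, each = n)
  if (!keep_cache) return(list(logits = logits))
  list(logits = logits,
       cache = list(x1 = x1, a1 = a1, pool = pool, p_dim = pd, x2 = x2,
                    a2 = a2, flat = flat, dm = dm, mask = mask, dmd = dmd,
                    n = n, h = h, w = wd))
}

# Backward pass from dL/dlogits; returns gradients matching the weight
# list layout.
qcnn_backward <- function(net, cache, dlogits) {
  w <- net$weights; spec <- net$spec
  n <- cache$n
  dWo <- crossprod(cache$dmd, dlogits)
  dbo <- colSums(dlogits)
  ddmd <- tcrossprod(dlogits, w$Wo)
  ddm <- if (is.null(cache$mask)) ddmd else ddmd * cache$mask
  ddm[cache$dm <= 0] <- 0
  dWd <- crossprod(cache$flat, ddm)
  dbd <- colSums(ddm)
  dflat <- tcrossprod(ddm, w$Wd)
  da2 <- dflat; dim(da2) <- c(nrow(cache$a2), ncol(cache$a2))
  da2[cache$a2 <= 0] <- 0
  dW2 <- crossprod(cache$x2, da2)
  db2 <- colSums(da2)
  dx2 <- tcrossprod(da2, w$W2)
  pd <- cache$p_dim
  dp <- col2im3(dx2, n, pd[2L], pd[3L], spec$conv_filters[1L])
  da1t <- if (is.null(cache$pool)) dp else maxpool2_backward(cache$pool, dp)
  da1 <- da1t; dim(da1) <- c(n * cache$h * cache$w, spec$conv_filters[1L])
  da1[cache$a1 <= 0] <- 0
  dW1 <- crossprod(cache$x1, da1)
  db1 <- colSums(da1)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, Wd = dWd, bd = dbd,
       Wo = dWo, bo = dbo)
}

#' Numerically stable softmax
#'
#' \eqn{p_i = \exp(h_i) / \sum_j \exp(h_j)}, computed max-shifted. Accepts
#' a vector or a matrix of row-wise logits.
#'
#' @param logits Numeric vector or matrix (rows = samples).
#' @return Probabilities of the same shape; rows sum to 1.
#' @export
softmax <- function(logits) {
  if (!all(is.finite(logits))) stop_invalid("softmax requires finite logits")
  if (is.matrix(logits)) {
    z <- logits - apply(logits, 1L, max)
    e <- exp(z)
    e / rowSums(e)
  } else {
    e <- exp(logits - max(logits))
    e / sum(e)
  }
}

#' Cross-entropy loss
#'
#' \eqn{-\sum_i y_i \log p_i} with probabilities clipped at `1e-12`, so a
#' zero probability on the true class yields a large finite loss.
#'
#' @param y One-hot label vector or matrix.
#' @param p Probability vector or matrix matching `y`.
#' @return Nonnegative scalar (mean over rows for matrices).
#' @export
cross_entropy <- function(y, p) {
  p <- pmax(p, 1e-12)
  if (is.matrix(y)) mean(-rowSums(y * log(p))) else -sum(y * log(p))
}

adam_step <- function(state, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    state$w[[nm]] <- state$w[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  state
}

#' Training configuration
#'
#' Defaults follow the reference recipe: Adam at learning rate 1e-3,
#' batch size 8, at most 100 epochs with early stopping (validation loss,
#' patience 10, best weights restored).
#'
#' @param batch_size Minibatch size.
#' @param max_epochs Epoch cap.
#' @param lr Adam learning rate.
#' @param patience Early-stopping patience in epochs; `Inf` disables.
#' @param val_fraction Fraction of training data held out for the early
#'   stopping monitor when no explicit validation set is supplied.
#' @return A list of class `train_config`.
#' @export
train_config <- function(batch_size = 8L, max_epochs = 100L, lr = 1e-3,
                         patience = 10L, val_fraction = 0.1) {
  structure(list(batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), lr = lr,
                 patience = patience, val_fraction = val_fraction),
            class = "train_config")
}

#' Train a convolutional classifier
#'
#' Minimizes cross-entropy (or, when `distill` and `teacher_logits` are
#' supplied, the combined distillation objective) by minibatch Adam.
#' Fully deterministic given `seed`: shuffling, dropout and
#' initialization all derive from it.
#'
#' @param spec A [qcnn_spec()], or an existing `qcnn` to continue from.
#' @param x Input array `(N, H, W, C)` (a 3D array is treated as 1
#'   channel).
#' @param y Integer class labels, 0-based.
#' @param x_val,y_val Optional validation set for the early-stopping
#'   monitor; defaults to an internal split of `val_fraction`.
#' @param teacher_logits Optional `N x K` matrix of frozen-teacher logits
#'   aligned with `x` (and `teacher_logits_val` with `x_val`); enables
#'   distillation.
#' @param teacher_logits_val Validation-set teacher logits.
#' @param distill A [distill_config()] when distilling, else `NULL`.
#' @param config A [train_config()].
#' @param seed Integer seed.
#' @param verbose Print per-epoch losses.
#' @return A trained `qcnn` with a `history` data frame (epoch,
#'   total_loss, ce_component, kl_component, val_loss, val_accuracy).
#' @export
qcnn_train <- function(spec, x, y, x_val = NULL, y_val = NULL,
                       teacher_logits = NULL, teacher_logits_val = NULL,
                       distill = NULL, config = train_config(), seed = 1L,
                       verbose = FALSE) {
  x <- as_input_array(x)
  net <- if (inherits(spec, "qcnn")) spec else qcnn_init(spec, seed = seed)
  spec <- net$spec
  n <- dim(x)[1L]
  if (length(y) != n) stop_invalid("x and y sizes differ")
  if (!is.null(teacher_logits) && nrow(teacher_logits) != n) {
    stop_invalid("teacher_logits must align with x")
  }
  distilling <- !is.null(distill) && !is.null(teacher_logits)
  yoh <- one_hot(y, spec$n_classes)

  hist <- list()
  with_seed(seed + 1L, {
    if (is.null(x_val)) {
      n_val <- max(1L, floor(config$val_fraction * n))
      vidx <- sample(n, n_val)
      x_val <- x[vidx, , , , drop = FALSE]; y_val <- y[vidx]
      if (distilling) teacher_logits_val <- teacher_logits[vidx, , drop = FALSE]
      tidx <- setdiff(seq_len(n), vidx)
      x <- x[tidx, , , , drop = FALSE]; y <- y[tidx]; yoh <- yoh[tidx, , drop = FALSE]
      if (distilling) teacher_logits <- teacher_logits[tidx, , drop = FALSE]
      n <- length(tidx)
    } else {
      x_val <- as_input_array(x_val)
    }
    yoh_val <- one_hot(y_val, spec$n_classes)

    opt <- list(w = net$weights,
                m = lapply(net$weights, function(z) z * 0),
                v = lapply(net$weights, function(z) z * 0), t = 0L)
    best_loss <- Inf; best_w <- opt$w; best_epoch <- 0L; wait <- 0L
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample(n)
      ep_tot <- ep_ce <- ep_kl <- 0
      for (b0 in seq(1L, n, by = config$batch_size)) {
        idx <- ord[b0:min(b0 + config$batch_size - 1L, n)]
        xb <- x[idx, , , , drop = FALSE]
        yb <- yoh[idx, , drop = FALSE]
        net$weights <- opt$w
        fw <- qcnn_forward(net, xb, train = TRUE, keep_cache = TRUE)
        ps <- softmax(fw$logits)
        ce <- cross_entropy(yb, ps)
        m <- length(idx)
        if (distilling) {
          tl <- teacher_logits[idx, , drop = FALSE]
          Tt <- distill$temperature
          kscale <- if (distill$squared_T_scaling) Tt^2 else 1
          tsoft <- softmax(tl / Tt)
          ssoft <- softmax(fw$logits / Tt)
          kl <- mean(rowSums(tsoft * (log(pmax(tsoft, 1e-12)) -
                                        log(pmax(ssoft, 1e-12)))))
          total <- distill$alpha * ce + (1 - distill$alpha) * kscale * kl
          dlog <- distill$alpha * (ps - yb) / m +
            (1 - distill$alpha) * kscale * (ssoft - tsoft) / (Tt * m)
        } else {
          kl <- 0
          total <- ce
          dlog <- (ps - yb) / m
        }
        grads <- qcnn_backward(net, fw$cache, dlog)
        opt <- adam_step(opt, grads, config$lr)
        ep_tot <- ep_tot + total * m; ep_ce <- ep_ce + ce * m
        ep_kl <- ep_kl + kl * m
      }
      net$weights <- opt$w
      vl <- qcnn_forward(net, x_val)$logits
      vp <- softmax(vl)
      vce <- cross_entropy(yoh_val, vp)
      if (distilling) {
        Tt <- distill$temperature
        kscale <- if (distill$squared_T_scaling) Tt^2 else 1
        tsv <- softmax(teacher_logits_val / Tt)
        ssv <- softmax(vl / Tt)
        vkl <- mean(rowSums(tsv * (log(pmax(tsv, 1e-12)) -
                                     log(pmax(ssv, 1e-12)))))
        vloss <- distill$alpha * vce + (1 - distill$alpha) * kscale * vkl
      } else {
        vloss <- vce
      }
      vacc <- mean(max.col(vp) - 1L == y_val)
      hist[[epoch]] <- data.frame(
        epoch = epoch, total_loss = ep_tot / n, ce_component = ep_ce / n,
        kl_component = ep_kl / n, val_loss = vloss, val_accuracy = vacc)
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f  val_loss %.4f  val_acc %.4f",
                        epoch, ep_tot / n, vloss, vacc))
      }
      if (vloss < best_loss - 1e-9) {
        best_loss <- vloss; best_w <- opt$w; best_epoch <- epoch; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
    net$weights <- best_w
    net$history <- do.call(rbind, hist)
    net$best_epoch <- best_epoch
    net$trained <- TRUE
  })
  net
}

as_input_array <- function(x) {
  if (inherits(x, "feature_map_archive")) x <- x$maps
  d <- dim(x)
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  x
}

#' Predict from a trained network
#'
#' @param object A `qcnn`.
#' @param newdata Input array `(N, H, W, C)` (3D arrays get one channel),
#'   or a `feature_map_archive`.
#' @param type `"class"` (0-based labels), `"prob"`, or `"logit"`.
#'   Dropout is disabled: repeated calls are identical.
#' @param ... Unused.
#' @return Vector of labels or matrix of probabilities/logits.
#' @export
predict.qcnn <- function(object, newdata, type = c("class", "prob", "logit"),
                         ...) {
  type <- match.arg(type)
  x <- as_input_array(newdata)
  logits <- qcnn_forward(object, x)$logits
  switch(type,
         logit = logits,
         prob = softmax(logits),
         class = max.col(softmax(logits)) - 1L)
}

#' @export
print.qcnn <- function(x, ...) {
  s <- x$spec
  cat(sprintf("<qcnn %s: input %s, Conv2D(%d/%d), dense %d, %d classes%s>\n",
              s$role, paste(s$input_shape, collapse = "x"),
              s$conv_filters[1L], s$conv_filters[2L], s$dense_units,
              s$n_classes, if (x$trained) ", trained" else ""))
  invisible(x)
}

#' @export
summary.qcnn <- function(object, ...) {
  print(object)
  np <- sum(vapply(object$weights, length, numeric(1)))
  cat(sprintf("  parameters: %s\n", format(np, big.mark = ",")))
  if (!is.null(object$history)) {
    h <- object$history
    cat(sprintf("  trained %d epoch(s); best epoch %d (val_loss %.4f, val_acc %.4f)\n",
                nrow(h), object$best_epoch,
                min(h$val_loss), h$val_accuracy[which.min(h$val_loss)]))
  }
  invisible(object)
}

#' Checksum of a network's weights
#'
#' Hash of the exact weight values; used to verify that a frozen teacher
#' is untouched by distillation.
#'
#' @param net A `qcnn`.
#' @return Hex string.
#' @export
qcnn_checksum <- function(net) object_hash(net$weights)

#' Save / load a network checkpoint
#'
#' Writes the weights as an RDS file plus a JSON sidecar describing the
#' architecture and seed.
#'
#' @param net A `qcnn`.
#' @param path Checkpoint path (`.rds`); the sidecar is `path + ".json"`.
#' @return `qcnn_load` returns the restored `qcnn`.
#' @export
qcnn_save <- function(net, path) {
  saveRDS(net, path)
  side <- list(role = net$spec$role, input_shape = net$spec$input_shape,
               n_classes = net$spec$n_classes,
               conv_filters = net$spec$conv_filters,
               dense_units = net$spec$dense_units,
               dropout_rate = net$spec$dropout_rate, seed = net$seed,
               trained = net$trained, checksum = qcnn_checksum(net))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname qcnn_save
#' @export
qcnn_load <- function(path) readRDS(path)
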