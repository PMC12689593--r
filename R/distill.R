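# Teacher-student knowledge distillation: the frozen teacher supplies
# temperature-softened targets and the student trains on
#   alpha * CE(y, softmax(S)) + (1 - alpha) * KL(soft(T) || soft(S)),
# the combined objective with T = 5 and alpha = 0.5 by default.

#' Distillation configuration
#'
#' @param temperature Softening temperature `T > 0` (default 5). Larger
#'   `T` flattens the teacher's distribution toward uniform, exposing
#'   inter-class similarity structure.
#' @param alpha Mixing weight in `[0, 1]` on the hard-label cross-entropy
#'   term (default 0.5); `1 - alpha` weights the KL term.
#' @param squared_T_scaling Multiply the KL term by `T^2` (the classical
#'   formulation's gradient-balancing factor; off by default, matching
#'   the plain combined loss).
#' @return A list of class `distill_config`.
#' @export
distill_config <- function(temperature = 5, alpha = 0.5,
                           squared_T_scaling = FALSE) {
  if (!is.numeric(temperature) || temperature <= 0) {
    stop_invalid("temperature must be > 0")
  }
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1) {
    stop_invalid("alpha must lie in [0, 1]")
  }
  structure(list(temperature = temperature, alpha = alpha,
                 squared_T_scaling = isTRUE(squared_T_scaling)),
            class = "distill_config")
}

#' Temperature-softened probabilities
#'
#' `softmax(logits / T)`. `T = 1` is the ordinary softmax; `T -> Inf`
#' approaches the uniform distribution.
#'
#' @param logits Numeric vector or row-wise matrix of logits.
#' @param temperature Positive temperature.
#' @return Probabilities of the same shape.
#' @export
softened_probs <- function(logits, temperature) {
  if (!is.numeric(temperature) || temperature <= 0) {
    stop_invalid("temperature must be > 0")
  }
  softmax(logits / temperature)
}

#' Kullback-Leibler divergence
#'
#' \eqn{\sum_i p_i \log(p_i / q_i)} with both arguments clipped at
#' `1e-12`. Direction is `KL(p || q)` with `p` the reference (the
#' teacher, in distillation). Nonnegative by Gibbs' inequality.
#'
#' @param p,q Probability vectors of equal length (or row-wise matrices;
#'   the mean row divergence is returned).
#' @return Nonnegative scalar.
#' @export
kl_divergence <- function(p, q) {
  if (length(p) != length(q)) stop_invalid("p and q must have equal length")
  pc <- pmax(p, 1e-12); qc <- pmax(q, 1e-12)
  if (is.matrix(p)) {
    mean(rowSums(p * (log(pc) - log(qc))))
  } else {
    sum(p * (log(pc) - log(qc)))
  }
}

#' Combined distillation loss
#'
#' `alpha * CE(y, softmax(S)) + (1 - alpha) * KL(soft(T) || soft(S))`
#' where `soft(.)` is [softened_probs()] at `cfg$temperature`; the KL term
#' is additionally multiplied by `T^2` iff `cfg$squared_T_scaling`.
#'
#' @param y One-hot label vector/matrix.
#' @param student_logits,teacher_logits Logit vectors/matrices of matching
#'   shape. Teacher logits must come from a frozen model (no gradients
#'   flow into them).
#' @param cfg A [distill_config()].
#' @return Nonnegative scalar loss.
#' @export
distill_loss <- function(y, student_logits, teacher_logits,
                         cfg = distill_config()) {
  if (!identical(dim(student_logits), dim(teacher_logits)) ||
      length(student_logits) != length(teacher_logits)) {
    stop_invalid("student and teacher logits must have the same shape")
  }
  ce <- cross_entropy(y, softmax(student_logits))
  kl <- kl_divergence(softened_probs(teacher_logits, cfg$temperature),
                      softened_probs(student_logits, cfg$temperature))
  kscale <- if (cfg$squared_T_scaling) cfg$temperature^2 else 1
  cfg$alpha * ce + (1 - cfg$alpha) * kscale * kl
}

#' Train a student under a frozen teacher
#'
#' Computes the teacher's logits once on its own inputs (the teacher and
#' student may consume different representations of the same samples:
#' standardized images vs. quantum feature maps), verifies by checksum
#' that the teacher's weights never change, and trains the student on the
#' combined objective with the reference recipe (Adam 1e-3, batch 8,
#' early stopping).
#'
#' @param teacher A trained `qcnn`.
#' @param teacher_x Teacher-view input array aligned with `student_x`.
#' @param student_spec A [qcnn_spec()] for the student.
#' @param student_x Student-view input array.
#' @param y 0-based integer labels.
#' @param cfg A [distill_config()].
#' @param config A [train_config()].
#' @param seed Integer seed.
#' @param verbose Print per-epoch losses.
#' @return The trained student `qcnn`; its `history` carries per-epoch
#'   total/CE/KL components.
#' @export
train_with_distillation <- function(teacher, teacher_x, student_spec,
                                    student_x, y, cfg = distill_config(),
                                    config = train_config(), seed = 1L,
                                    verbose = FALSE) {
  if (!inherits(teacher, "qcnn") || !isTRUE(teacher$trained)) {
    stop_invalid("teacher must be a trained qcnn")
  }
  before <- qcnn_checksum(teacher)
  tlogits <- predict(teacher, teacher_x, type = "logit")
  student <- qcnn_train(student_spec, student_x, y,
                        teacher_logits = tlogits, distill = cfg,
                        config = config, seed = seed, verbose = verbose)
  if (!identical(qcnn_checksum(teacher), before)) {
    stop("internal error: teacher weights changed during distillation")
  }
  student
}

#' Write a training history to CSV
#'
#' Columns: epoch, total_loss, ce_component, kl_component, val_loss,
#' val_accuracy.
#'
#' @param net A trained `qcnn`.
#' @param path Output CSV path.
#' @export
write_history_csv <- function(net, path) {
  utils::write.csv(net$history, path, row.names = FALSE)
  invisible(path)
}
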