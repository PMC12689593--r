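# Evaluation protocol and metrics: repeated stratified 80/20 hold-out,
# confusion matrix, per-class precision/recall/F1, macro and
# support-weighted averages, accuracy, and one-vs-rest AUC by the
# Mann-Whitney rank statistic. Everything is computed from counts here;
# tests cross-check against independent reference implementations.

#' Hold-out split protocol
#'
#' @param test_fraction Fraction held out for testing (default 0.2).
#' @param n_repeats Number of repeated splits (default 10).
#' @param stratified Preserve class proportions within each split.
#' @param base_seed Repeat `r` uses seed `base_seed + r`.
#' @return A list of class `split_protocol`.
#' @export
split_protocol <- function(test_fraction = 0.2, n_repeats = 10L,
                           stratified = TRUE, base_seed = 1L) {
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop_invalid("test_fraction must lie in (0, 1)")
  }
  if (!is_count(n_repeats, 1L)) stop_invalid("n_repeats must be >= 1")
  structure(list(test_fraction = test_fraction,
                 n_repeats = as.integer(n_repeats),
                 stratified = isTRUE(stratified),
                 base_seed = as.integer(base_seed)),
            class = "split_protocol")
}

#' Generate train/test index splits
#'
#' Each repeat partitions the indices into disjoint train and test sets;
#' stratified splits allocate `round(test_fraction * n_k)` test samples
#' per class, so class proportions carry over within rounding.
#'
#' @param labels 0-based integer class labels (or a `labeled_dataset`).
#' @param protocol A [split_protocol()].
#' @return List of `protocol$n_repeats` lists with 1-based integer
#'   vectors `train` and `test`.
#' @export
make_splits <- function(labels, protocol = split_protocol()) {
  if (inherits(labels, "labeled_dataset")) labels <- labels$labels
  n <- length(labels)
  if (protocol$stratified &&
      any(table(labels) < 2L)) {
    stop_invalid("stratified splitting needs >= 2 members per class")
  }
  lapply(seq_len(protocol$n_repeats), function(r) {
    with_seed(protocol$base_seed + r, {
      if (protocol$stratified) {
        test <- integer(0)
        for (k in sort(unique(labels))) {
          members <- which(labels == k)
          n_test <- max(1L, round(protocol$test_fraction * length(members)))
          test <- c(test, sample(members, n_test))
        }
        test <- sort(test)
      } else {
        test <- sort(sample(n, max(1L, round(protocol$test_fraction * n))))
      }
      list(train = setdiff(seq_len(n), test), test = test)
    })
  })
}

#' Confusion matrix
#'
#' Entry `(i, j)` counts samples with true class `i` predicted as class
#' `j` (0-based classes; row/column `k` is class `k - 1`).
#'
#' @param y_true,y_pred 0-based integer label vectors.
#' @param n_classes Number of classes `K`.
#' @return `K x K` integer matrix.
#' @export
confusion_matrix <- function(y_true, y_pred, n_classes) {
  if (length(y_true) != length(y_pred)) stop_invalid("label lengths differ")
  if (any(c(y_true, y_pred) < 0L) || any(c(y_true, y_pred) >= n_classes)) {
    stop_invalid("labels must lie in [0, %d)", n_classes)
  }
  cm <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(y_true)) {
    cm[y_true[i] + 1L, y_pred[i] + 1L] <- cm[y_true[i] + 1L, y_pred[i] + 1L] + 1L
  }
  cm
}

#' Per-class and averaged classification metrics from a confusion matrix
#'
#' Computes precision `TP/(TP+FP)`, recall `TP/(TP+FN)` and
#' `F1 = 2PR/(P+R)` per class, overall accuracy (trace over total), the
#' macro average (unweighted class mean) and the support-weighted
#' average. Zero denominators yield 0 with a warning. The weighted recall
#' equals accuracy identically.
#'
#' @param confusion Nonnegative integer `K x K` matrix, rows = true.
#' @return List of class `classification_report`: `per_class` data frame
#'   (class, support, precision, recall, f1), `accuracy`, `macro_avg` and
#'   `weighted_avg` named vectors.
#' @export
classification_report <- function(confusion) {
  K <- nrow(confusion)
  tp <- diag(confusion)
  support <- rowSums(confusion)
  pred_tot <- colSums(confusion)
  n <- sum(confusion)
  div0 <- function(num, den, what) {
    out <- ifelse(den > 0, num / den, 0)
    if (any(den == 0)) {
      warning(sprintf("%s undefined for class(es) %s; reported as 0", what,
                      paste(which(den == 0) - 1L, collapse = ", ")),
              call. = FALSE)
    }
    out
  }
  precision <- div0(tp, pred_tot, "precision")
  recall <- div0(tp, support, "recall")
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  per_class <- data.frame(class = seq_len(K) - 1L, support = support,
                          precision = precision, recall = recall, f1 = f1)
  w <- support / n
  structure(list(
    per_class = per_class,
    accuracy = sum(tp) / n,
    macro_avg = c(precision = mean(precision), recall = mean(recall),
                  f1 = mean(f1)),
    # w_k * recall_k = tp_k / n; summing in that cancelled form keeps the
    # weighted-recall == accuracy identity exact in floating point
    weighted_avg = c(precision = sum(w * precision),
                     recall = sum(tp[support > 0]) / n,
                     f1 = sum(w * f1))
  ), class = "classification_report")
}

#' One-vs-rest ROC AUC by the rank statistic
#'
#' Mann-Whitney AUC with half-credit for ties: the probability that a
#' random positive's score for `class_k` exceeds a random negative's.
#' Invariant under strictly monotone score transforms.
#'
#' @param y_true 0-based integer labels.
#' @param prob_matrix `n x K` score matrix (column `k + 1` scores class
#'   `k`).
#' @param class_k 0-based class treated as positive.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc_ovr <- function(y_true, prob_matrix, class_k) {
  scores <- prob_matrix[, class_k + 1L]
  pos <- y_true == class_k
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) {
    stop_invalid("AUC undefined: class %d needs at least one positive and one negative",
                 class_k)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Build a full evaluation report for one split
#'
#' @param y_true 0-based labels of the test set.
#' @param prob_matrix `n x K` predicted probabilities.
#' @param n_classes Number of classes.
#' @param split_id Identifier of the repeat this report belongs to.
#' @return List of class `eval_report`: `confusion`, the
#'   [classification_report()] fields, `auc_per_class` (NA for classes
#'   absent from `y_true`), and `split_id`.
#' @export
eval_report <- function(y_true, prob_matrix, n_classes, split_id = 1L) {
  y_pred <- max.col(prob_matrix) - 1L
  cm <- confusion_matrix(y_true, y_pred, n_classes)
  rep <- classification_report(cm)
  auc <- vapply(seq_len(n_classes) - 1L, function(k) {
    if (sum(y_true == k) == 0L || sum(y_true != k) == 0L) return(NA_real_)
    roc_auc_ovr(y_true, prob_matrix, k)
  }, numeric(1))
  structure(list(confusion = cm, per_class = rep$per_class,
                 accuracy = rep$accuracy, macro_avg = rep$macro_avg,
                 weighted_avg = rep$weighted_avg, auc_per_class = auc,
                 split_id = split_id, n_test = length(y_true)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report: split %s, n = %d, accuracy %.4f>\n",
              format(x$split_id), x$n_test, x$accuracy))
  df <- x$per_class
  df$auc <- x$auc_per_class
  print(df, row.names = FALSE, digits = 4)
  cat(sprintf("  macro    P %.4f  R %.4f  F1 %.4f\n",
              x$macro_avg["precision"], x$macro_avg["recall"],
              x$macro_avg["f1"]))
  cat(sprintf("  weighted P %.4f  R %.4f  F1 %.4f\n",
              x$weighted_avg["precision"], x$weighted_avg["recall"],
              x$weighted_avg["f1"]))
  invisible(x)
}

#' Aggregate evaluation reports across repeats
#'
#' Elementwise mean and standard deviation of accuracy, per-class
#' metrics, macro/weighted averages and AUCs across repeated splits.
#'
#' @param reports List of [eval_report()] objects with a common class
#'   count.
#' @return List of class `eval_summary` with `mean` and `sd` components
#'   mirroring the report structure, plus `n_repeats`.
#' @export
aggregate_repeats <- function(reports) {
  if (length(reports) == 0L) stop_invalid("need at least one report")
  K <- nrow(reports[[1L]]$confusion)
  if (!all(vapply(reports, function(r) nrow(r$confusion) == K, logical(1)))) {
    stop_invalid("reports disagree on the number of classes")
  }
  pull <- function(f) t(vapply(reports, f, numeric(length(f(reports[[1L]])))))
  metrics <- list(
    accuracy = vapply(reports, function(r) r$accuracy, numeric(1)),
    precision = pull(function(r) r$per_class$precision),
    recall = pull(function(r) r$per_class$recall),
    f1 = pull(function(r) r$per_class$f1),
    macro = pull(function(r) r$macro_avg),
    weighted = pull(function(r) r$weighted_avg),
    auc = pull(function(r) r$auc_per_class)
  )
  sd0 <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) > 1L) stats::sd(x) else 0
  }
  colsd <- function(m) apply(m, 2L, sd0)
  structure(list(
    n_repeats = length(reports),
    mean = lapply(metrics, function(m) {
      if (is.matrix(m)) colMeans(m, na.rm = TRUE) else mean(m, na.rm = TRUE)
    }),
    sd = lapply(metrics, function(m) if (is.matrix(m)) colsd(m) else sd0(m))
  ), class = "eval_summary")
}

#' @export
print.eval_summary <- function(x, ...) {
  cat(sprintf("<eval_summary over %d repeat(s)>\n", x$n_repeats))
  cat(sprintf("  accuracy %.4f (sd %.4f)\n", x$mean$accuracy, x$sd$accuracy))
  cat(sprintf("  macro    P %.4f  R %.4f  F1 %.4f\n",
              x$mean$macro["precision"], x$mean$macro["recall"],
              x$mean$macro["f1"]))
  cat(sprintf("  weighted P %.4f  R %.4f  F1 %.4f\n",
              x$mean$weighted["precision"], x$mean$weighted["recall"],
              x$mean$weighted["f1"]))
  invisible(x)
}

# ---- report writers --------------------------------------------------------

#' Write evaluation artifacts
#'
#' `write_classification_csv` writes the per-class table (class, P, R,
#' FS); `write_summary_csv` writes one explicit macro row and one
#' weighted row (accuracy, P, R, FS); `write_confusion_json` writes the
#' confusion matrix; `write_roc_csv` writes one-vs-rest ROC points per
#' class.
#'
#' @param report An `eval_report`.
#' @param path Output file path.
#' @param class_names Optional class name vector.
#' @export
write_classification_csv <- function(report, path, class_names = NULL) {
  df <- report$per_class
  cls <- if (is.null(class_names)) as.character(df$class) else class_names
  out <- data.frame(class = cls, P = df$precision, R = df$recall, FS = df$f1)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_classification_csv
#' @param label Dataset/arm label written in the first column.
#' @export
write_summary_csv <- function(report, path, label = "dataset") {
  out <- data.frame(
    dataset = label, average = c("macro", "weighted"),
    accuracy = report$accuracy,
    P = c(report$macro_avg["precision"], report$weighted_avg["precision"]),
    R = c(report$macro_avg["recall"], report$weighted_avg["recall"]),
    FS = c(report$macro_avg["f1"], report$weighted_avg["f1"]))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_classification_csv
#' @export
write_confusion_json <- function(report, path, class_names = NULL) {
  jsonlite::write_json(list(confusion = report$confusion,
                            class_names = class_names,
                            n_test = report$n_test),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_classification_csv
#' @param y_true,prob_matrix Labels and scores used to trace the curves.
#' @export
write_roc_csv <- function(y_true, prob_matrix, path) {
  K <- ncol(prob_matrix)
  rows <- list()
  for (k in seq_len(K) - 1L) {
    pos <- y_true == k
    if (sum(pos) == 0L || sum(!pos) == 0L) next
    sc <- prob_matrix[, k + 1L]
    th <- sort(unique(c(-Inf, sc, Inf)), decreasing = TRUE)
    tpr <- vapply(th, function(t) mean(sc[pos] >= t), numeric(1))
    fpr <- vapply(th, function(t) mean(sc[!pos] >= t), numeric(1))
    rows[[length(rows) + 1L]] <- data.frame(class = k, threshold = th,
                                            fpr = fpr, tpr = tpr)
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
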