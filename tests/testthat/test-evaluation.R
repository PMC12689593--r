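test_that("hold-out splits are disjoint, complete, sized and seeded", {
  labels <- rep(0:3, times = c(30, 10, 40, 20))
  proto <- split_protocol(test_fraction = 0.2, n_repeats = 3, base_seed = 9)
  splits <- make_splits(labels, proto)
  expect_length(splits, 3)
  for (s in splits) {
    expect_length(s$test, 20)
    expect_length(intersect(s$train, s$test), 0)
    expect_setequal(c(s$train, s$test), seq_along(labels))
    # stratification preserves proportions within rounding
    expect_equal(as.integer(table(labels[s$test])), c(6L, 2L, 8L, 4L))
  }
  splits2 <- make_splits(labels, proto)
  expect_identical(splits, splits2)
  expect_error(make_splits(c(0L, 0L, 1L), split_protocol()), ">= 2")
})

test_that("confusion matrices count true-by-predicted pairs", {
  perfect <- confusion_matrix(c(0, 1, 2, 0), c(0, 1, 2, 0), 3)
  expect_equal(perfect, diag(c(2L, 1L, 1L)))
  cm <- confusion_matrix(c(0, 0, 1, 1), c(0, 1, 1, 1), 2)
  expect_equal(cm, matrix(c(1L, 0L, 1L, 2L), 2, 2))
  expect_equal(sum(cm), 4L)
  expect_error(confusion_matrix(c(0, 5), c(0, 1), 2), "lie in")
})

test_that("the classification report evaluates the P/R/F1 formulas", {
  ident <- classification_report(diag(c(5L, 3L)))
  expect_equal(ident$accuracy, 1)
  expect_true(all(ident$per_class$f1 == 1))
  cm <- matrix(c(1L, 0L, 1L, 2L), 2, 2)
  rep <- classification_report(cm)
  expect_equal(rep$per_class$precision, c(1, 2 / 3))
  expect_equal(rep$per_class$recall, c(0.5, 1))
  expect_equal(rep$per_class$f1, c(2 / 3, 0.8))
  expect_equal(rep$accuracy, 0.75)
  expect_equal(unname(rep$macro_avg["f1"]), (2 / 3 + 0.8) / 2)
  # zero-denominator policy: 0 with a warning
  cm0 <- matrix(c(2L, 0L, 0L, 0L), 2, 2)
  w <- capture_warnings(r0 <- classification_report(cm0))
  expect_length(w, 2)  # both precision and recall undefined for class 1
  expect_match(w, "undefined", all = TRUE)
  expect_equal(r0$per_class$precision[2], 0)
  expect_equal(r0$per_class$recall[2], 0)
})

test_that("weighted recall equals accuracy on random confusions", {
  set.seed(14)
  for (i in 1:100) {
    K <- sample(2:5, 1)
    cm <- matrix(rpois(K * K, 3) + diag(K), K, K)
    storage.mode(cm) <- "integer"
    if (any(rowSums(cm) == 0)) next
    rep <- suppressWarnings(classification_report(cm))
    expect_equal(unname(rep$weighted_avg["recall"]), rep$accuracy,
                 tolerance = 1e-14)
  }
})

test_that("rank-statistic AUC handles perfect, inverted and tied scores", {
  y <- c(0L, 0L, 1L, 1L)
  perfect <- cbind(c(0.9, 0.8, 0.1, 0.2), c(0.1, 0.2, 0.9, 0.8))
  expect_equal(roc_auc_ovr(y, perfect, 0), 1)
  expect_equal(roc_auc_ovr(y, perfect, 1), 1)
  expect_equal(roc_auc_ovr(y, perfect[, c(2, 1)], 0), 0)
  ties <- cbind(rep(0.5, 4), rep(0.5, 4))
  expect_equal(roc_auc_ovr(y, ties, 0), 0.5)
  expect_error(roc_auc_ovr(c(0L, 0L), perfect[1:2, ], 1), "undefined")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(21)
  y <- sample(0:1, 40, replace = TRUE, prob = c(0.6, 0.4))
  sc <- stats::runif(40)
  m <- cbind(1 - sc, sc)
  a1 <- roc_auc_ovr(y, m, 1)
  a2 <- roc_auc_ovr(y, cbind(1 - sc, exp(3 * sc)), 1)
  a3 <- roc_auc_ovr(y, cbind(1 - sc, rank(sc)), 1)
  expect_equal(a1, a2, tolerance = 1e-14)
  expect_equal(a1, a3, tolerance = 1e-14)
})

test_that("metrics match independent reference implementations", {
  skip_if_not_installed("caret")
  skip_if_not_installed("pROC")
  set.seed(31)
  for (i in 1:100) {
    K <- sample(2:4, 1)
    n <- sample(30:60, 1)
    y <- c(seq_len(K) - 1L, sample(0:(K - 1), n - K, replace = TRUE))
    pred <- c(seq_len(K) - 1L, sample(0:(K - 1), n - K, replace = TRUE))
    cm <- confusion_matrix(y, pred, K)
    rep <- suppressWarnings(classification_report(cm))
    ref <- caret::confusionMatrix(
      factor(pred, levels = 0:(K - 1)), factor(y, levels = 0:(K - 1)),
      mode = "prec_recall")
    by <- ref$byClass
    if (K == 2) {
      # recompute both classes one-vs-rest for the binary case
      for (k in 0:1) {
        r2 <- caret::confusionMatrix(
          factor(pred == k, levels = c(TRUE, FALSE)),
          factor(y == k, levels = c(TRUE, FALSE)), mode = "prec_recall")
        p_ref <- unname(r2$byClass["Precision"])
        r_ref <- unname(r2$byClass["Recall"])
        if (!is.na(p_ref)) expect_equal(rep$per_class$precision[k + 1], p_ref,
                                        tolerance = 1e-10)
        if (!is.na(r_ref)) expect_equal(rep$per_class$recall[k + 1], r_ref,
                                        tolerance = 1e-10)
      }
    } else {
      for (k in seq_len(K)) {
        p_ref <- unname(by[k, "Precision"]); r_ref <- unname(by[k, "Recall"])
        f_ref <- unname(by[k, "F1"])
        if (!is.na(p_ref)) expect_equal(rep$per_class$precision[k], p_ref,
                                        tolerance = 1e-10)
        if (!is.na(r_ref)) expect_equal(rep$per_class$recall[k], r_ref,
                                        tolerance = 1e-10)
        if (!is.na(f_ref)) expect_equal(rep$per_class$f1[k], f_ref,
                                        tolerance = 1e-10)
      }
    }
    expect_equal(rep$accuracy, unname(ref$overall["Accuracy"]),
                 tolerance = 1e-10)
    # AUC against pROC on random scores
    scores <- matrix(stats::runif(n * K), n, K)
    scores <- scores / rowSums(scores)
    for (k in 0:(K - 1)) {
      a_ref <- suppressMessages(as.numeric(
        pROC::auc(pROC::roc(y == k, scores[, k + 1], quiet = TRUE,
                            direction = "<"))))
      expect_equal(roc_auc_ovr(y, scores, k), a_ref, tolerance = 1e-10)
    }
  }
})

test_that("repeat aggregation averages elementwise and ignores order", {
  set.seed(41)
  mk <- function(seed) {
    set.seed(seed)
    y <- sample(0:2, 30, replace = TRUE)
    pr <- matrix(stats::runif(90), 30, 3); pr <- pr / rowSums(pr)
    eval_report(y, pr, 3, split_id = seed)
  }
  r1 <- mk(1); r2 <- mk(2); r3 <- mk(3)
  single <- aggregate_repeats(list(r1))
  expect_equal(single$mean$accuracy, r1$accuracy)
  expect_equal(single$sd$accuracy, 0)
  two <- aggregate_repeats(list(r1, r2))
  expect_equal(two$mean$accuracy, (r1$accuracy + r2$accuracy) / 2)
  a <- aggregate_repeats(list(r1, r2, r3))
  b <- aggregate_repeats(list(r3, r1, r2))
  expect_equal(a$sd, b$sd)
  expect_equal(a$mean, b$mean)
})

test_that("report writers emit the tabular artifacts", {
  set.seed(51)
  y <- sample(0:3, 80, replace = TRUE)
  pr <- matrix(stats::runif(320), 80, 4); pr <- pr / rowSums(pr)
  rep <- eval_report(y, pr, 4)
  d <- tempfile(); dir.create(d)
  write_classification_csv(rep, file.path(d, "pc.csv"),
                           class_names = c("m", "mo", "nd", "vd"))
  pc <- utils::read.csv(file.path(d, "pc.csv"))
  expect_equal(names(pc), c("class", "P", "R", "FS"))
  expect_equal(nrow(pc), 4)
  write_summary_csv(rep, file.path(d, "sum.csv"), label = "phantom")
  sm <- utils::read.csv(file.path(d, "sum.csv"))
  expect_equal(sm$average, c("macro", "weighted"))
  expect_equal(sm$R[2], rep$accuracy, tolerance = 1e-12)
  write_confusion_json(rep, file.path(d, "cm.json"))
  cj <- jsonlite::read_json(file.path(d, "cm.json"), simplifyVector = TRUE)
  expect_equal(sum(unlist(cj$confusion)), 80)
  write_roc_csv(y, pr, file.path(d, "roc.csv"))
  roc <- utils::read.csv(file.path(d, "roc.csv"))
  expect_true(all(c("class", "fpr", "tpr") %in% names(roc)))
  expect_true(all(roc$tpr >= 0 & roc$tpr <= 1))
})
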