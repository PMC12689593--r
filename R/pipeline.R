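# Config-driven end-to-end experiments: phantom generation -> rebalance
# -> preprocessing -> quanvolution -> teacher training -> student training
# with and without knowledge distillation -> repeated evaluation, with a
# reproducibility manifest. All stages derive their randomness from the
# single global seed, so a run is bit-reproducible.

run_config_defaults <- function() {
  list(
    seed = 1L,
    n_total = 1600L,
    image_side = 28L,
    n_classes = 4L,
    class_proportions = c(0.14, 0.01, 0.50, 0.35),
    noise_sd = 0.05,
    rebalance_to = NULL,       # per-class targets; NULL = max observed count
    target_side = 28L,
    roi_side = 14L,
    patch_side = 2L,
    reduction = "row_mean",
    n_layers = 2L,
    pqc_seed = NULL,           # defaults to seed
    trainable_pqc = FALSE,
    teacher_input = "roi",     # "roi" (standardized ROI), "image", "quantum"
    dense_units = 64L,
    dropout = 0.5,
    batch_size = 8L,
    max_epochs = 100L,
    lr = 1e-3,
    optimizer = "adam",
    patience = 10L,
    temperature = 5,
    alpha = 0.5,
    squared_T_scaling = FALSE,
    test_fraction = 0.2,
    n_repeats = 10L,
    stratified = TRUE,
    out_dir = NULL
  )
}

#' Validate and complete a run configuration
#'
#' Fills defaults (temperature 5, alpha 0.5, batch size 8, learning rate
#' 1e-3, Adam, dropout 0.5, 100 epochs with early stopping), rejects
#' unknown keys with a nearest-match suggestion, and reports all range
#' violations at once.
#'
#' @param raw Named list of overrides, or a YAML file path, or `NULL`
#'   for the full default configuration.
#' @return A validated list of class `run_config`.
#' @export
validate_config <- function(raw = NULL) {
  if (is.character(raw) && length(raw) == 1L) raw <- yaml::read_yaml(raw)
  if (is.null(raw)) raw <- list()
  defaults <- run_config_defaults()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown) > 0L) {
    hints <- vapply(unknown, function(k) {
      d <- utils::adist(k, names(defaults))
      best <- names(defaults)[which.min(d)]
      if (min(d) <= max(3L, nchar(k) %/% 2L)) {
        sprintf("'%s' (did you mean '%s'?)", k, best)
      } else sprintf("'%s'", k)
    }, character(1))
    stop_invalid("unknown config key(s): %s", paste(hints, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, raw)
  problems <- character(0)
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(is_count(cfg$seed, 0L), "seed must be a nonnegative integer")
  chk(is_count(cfg$n_total, cfg$n_classes),
      "n_total must be an integer >= n_classes")
  chk(is_count(cfg$image_side) && cfg$image_side %% 2L == 0L,
      "image_side must be a positive even integer")
  chk(length(cfg$class_proportions) == cfg$n_classes &&
        abs(sum(cfg$class_proportions) - 1) < 1e-9,
      "class_proportions must sum to 1 with one entry per class")
  chk(cfg$noise_sd >= 0, "noise_sd must be >= 0")
  chk(cfg$roi_side %% cfg$patch_side == 0L,
      "roi_side must be divisible by patch_side")
  chk(cfg$temperature > 0, "temperature must be > 0")
  chk(cfg$alpha >= 0 && cfg$alpha <= 1, "alpha must lie in [0, 1]")
  chk(cfg$dropout >= 0 && cfg$dropout < 1, "dropout must lie in [0, 1)")
  chk(cfg$lr > 0, "lr must be > 0")
  chk(is_count(cfg$batch_size), "batch_size must be a positive integer")
  chk(is_count(cfg$max_epochs), "max_epochs must be a positive integer")
  chk(cfg$test_fraction > 0 && cfg$test_fraction < 1,
      "test_fraction must lie in (0, 1)")
  chk(is_count(cfg$n_repeats), "n_repeats must be >= 1")
  chk(identical(cfg$optimizer, "adam"), "optimizer must be 'adam'")
  chk(cfg$teacher_input %in% c("roi", "image", "quantum"),
      "teacher_input must be one of 'roi', 'image', 'quantum'")
  if (length(problems) > 0L) {
    stop_invalid("invalid configuration:\n  - %s",
                 paste(problems, collapse = "\n  - "))
  }
  if (is.null(cfg$pqc_seed)) cfg$pqc_seed <- cfg$seed
  structure(cfg, class = "run_config")
}

# Teacher-view input tensor: per-image standardization against its own
# statistics, at the configured spatial view.
teacher_inputs <- function(dataset, cfg, pre, archive) {
  if (cfg$teacher_input == "quantum") return(archive$maps)
  n <- dim(dataset$images)[1L]
  side <- if (cfg$teacher_input == "roi") cfg$roi_side else cfg$target_side
  out <- array(0, dim = c(n, side, side, 1L))
  for (i in seq_len(n)) {
    img <- resize_bilinear(dataset$images[i, , ], cfg$target_side)
    if (cfg$teacher_input == "roi") img <- center_crop(img, cfg$roi_side)
    out[i, , , 1L] <- standardize(img)$pixels
  }
  out
}

#' Run a full experiment
#'
#' Executes the pipeline end to end: generates phantoms, rebalances the
#' classes, quanvolves every image, and per split repeat trains the
#' teacher, a student without distillation, and a student with
#' distillation, evaluating each on the held-out test set. Writes
#' per-class and summary CSVs, confusion matrices, ROC points, training
#' histories and a reproducibility manifest under `cfg$out_dir` when set.
#'
#' @param cfg A [validate_config()] result (or a raw list / YAML path,
#'   validated on entry).
#' @param verbose Print stage progress.
#' @return List of class `run_result`: per-repeat `eval_report`s for
#'   `teacher`, `student_nokd`, `student_kd`, their [aggregate_repeats()]
#'   summaries, and the manifest.
#' @export
run_experiment <- function(cfg = NULL, verbose = FALSE) {
  if (!inherits(cfg, "run_config")) cfg <- validate_config(cfg)
  say <- function(...) if (verbose) message(sprintf(...))
  t_start <- Sys.time()

  say("stage synth: %d images", cfg$n_total)
  spec <- phantom_spec(image_side = cfg$image_side, n_classes = cfg$n_classes,
                       class_proportions = cfg$class_proportions,
                       noise_sd = cfg$noise_sd, seed = cfg$seed)
  dataset <- generate_phantoms(spec, cfg$n_total)

  targets <- cfg$rebalance_to
  if (is.null(targets)) targets <- max(table(dataset$labels))
  say("stage rebalance: targets %s", paste(targets, collapse = "/"))
  dataset <- rebalance_dataset(dataset, targets, seed = cfg$seed + 1L)

  pre <- preprocess_config(target_side = cfg$target_side,
                           roi_side = cfg$roi_side,
                           patch_side = cfg$patch_side,
                           reduction = cfg$reduction)
  pqc <- pqc_params(n_qubits = 2L, n_layers = cfg$n_layers,
                    seed = cfg$pqc_seed, trainable = cfg$trainable_pqc)
  say("stage quanvolve: %d images -> %dx%dx2 maps",
      dim(dataset$images)[1L], cfg$roi_side %/% 2L, cfg$roi_side %/% 2L)
  archive <- quanvolve_dataset(dataset, pqc, pre)
  tx <- teacher_inputs(dataset, cfg, pre, archive)

  proto <- split_protocol(test_fraction = cfg$test_fraction,
                          n_repeats = cfg$n_repeats,
                          stratified = cfg$stratified,
                          base_seed = cfg$seed + 100L)
  splits <- make_splits(dataset$labels, proto)
  tc <- train_config(batch_size = cfg$batch_size, max_epochs = cfg$max_epochs,
                     lr = cfg$lr, patience = cfg$patience)
  dcfg <- distill_config(temperature = cfg$temperature, alpha = cfg$alpha,
                         squared_T_scaling = cfg$squared_T_scaling)
  g <- cfg$roi_side %/% 2L
  t_shape <- dim(tx)[2:4]

  out <- list(teacher = list(), student_nokd = list(), student_kd = list())
  histories <- list()
  for (r in seq_along(splits)) {
    tr <- splits[[r]]$train; te <- splits[[r]]$test
    ytr <- dataset$labels[tr]; yte <- dataset$labels[te]
    say("repeat %d/%d: train teacher", r, length(splits))
    teacher <- qcnn_train(
      qcnn_spec("teacher", input_shape = t_shape, n_classes = cfg$n_classes,
                dense_units = cfg$dense_units, dropout_rate = cfg$dropout),
      tx[tr, , , , drop = FALSE], ytr, config = tc, seed = cfg$seed + 10L + r)
    say("repeat %d/%d: train student (no KD)", r, length(splits))
    student0 <- qcnn_train(
      qcnn_spec("student", input_shape = c(g, g, 2L),
                n_classes = cfg$n_classes, dense_units = cfg$dense_units,
                dropout_rate = cfg$dropout),
      archive$maps[tr, , , , drop = FALSE], ytr, config = tc,
      seed = cfg$seed + 20L + r)
    say("repeat %d/%d: train student (KD)", r, length(splits))
    student1 <- train_with_distillation(
      teacher, tx[tr, , , , drop = FALSE],
      qcnn_spec("student", input_shape = c(g, g, 2L),
                n_classes = cfg$n_classes, dense_units = cfg$dense_units,
                dropout_rate = cfg$dropout),
      archive$maps[tr, , , , drop = FALSE], ytr, cfg = dcfg, config = tc,
      seed = cfg$seed + 20L + r)

    pt <- predict(teacher, tx[te, , , , drop = FALSE], type = "prob")
    p0 <- predict(student0, archive$maps[te, , , , drop = FALSE], type = "prob")
    p1 <- predict(student1, archive$maps[te, , , , drop = FALSE], type = "prob")
    out$teacher[[r]] <- eval_report(yte, pt, cfg$n_classes, split_id = r)
    out$student_nokd[[r]] <- eval_report(yte, p0, cfg$n_classes, split_id = r)
    out$student_kd[[r]] <- eval_report(yte, p1, cfg$n_classes, split_id = r)
    histories[[r]] <- list(teacher = teacher$history,
                           student_nokd = student0$history,
                           student_kd = student1$history)
    if (r == 1L && !is.null(cfg$out_dir)) {
      probs <- list(teacher = pt, student_nokd = p0, student_kd = p1)
      dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
      for (arm in names(probs)) {
        write_roc_csv(yte, probs[[arm]],
                      file.path(cfg$out_dir, sprintf("roc_%s.csv", arm)))
      }
    }
  }

  manifest <- list(
    config = unclass(cfg), config_hash = object_hash(unclass(cfg)),
    pqc_thetas = as.numeric(pqc$thetas),
    n_images = dim(dataset$images)[1L],
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("quanvolve")),
    elapsed_sec = as.numeric(difftime(Sys.time(), t_start, units = "secs")))

  result <- structure(list(
    reports = out,
    summary = lapply(out, aggregate_repeats),
    histories = histories,
    manifest = manifest,
    class_names = dataset$class_names
  ), class = "run_result")

  if (!is.null(cfg$out_dir)) write_run_dir(result, cfg$out_dir)
  result
}

# Write the Tables-shaped CSVs, confusion JSON and manifest for a run.
write_run_dir <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (arm in names(result$reports)) {
    rep1 <- result$reports[[arm]][[1L]]
    write_classification_csv(
      rep1, file.path(dir, sprintf("per_class_%s.csv", arm)),
      class_names = result$class_names)
    write_confusion_json(
      rep1, file.path(dir, sprintf("confusion_%s.json", arm)),
      class_names = result$class_names)
    s <- result$summary[[arm]]
    out <- data.frame(
      arm = arm, average = c("macro", "weighted"),
      accuracy = s$mean$accuracy,
      P = c(s$mean$macro["precision"], s$mean$weighted["precision"]),
      R = c(s$mean$macro["recall"], s$mean$weighted["recall"]),
      FS = c(s$mean$macro["f1"], s$mean$weighted["f1"]),
      accuracy_sd = s$sd$accuracy)
    utils::write.csv(out, file.path(dir, sprintf("summary_%s.csv", arm)),
                     row.names = FALSE)
  }
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("<run_result: %d repeat(s)>\n",
              x$summary$teacher$n_repeats))
  for (arm in names(x$summary)) {
    s <- x$summary[[arm]]
    cat(sprintf("  %-13s accuracy %.4f (sd %.4f)  macro-F1 %.4f\n", arm,
                s$mean$accuracy, s$sd$accuracy, s$mean$macro["f1"]))
  }
  invisible(x)
}
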