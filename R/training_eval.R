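# Five-fold cross-validated training/evaluation with the four performance
# metrics (accuracy, specificity, sensitivity, F1), and orchestration of
# whole studies and layer-ablation experiments.
#
# Binary tasks treat the seizure class (highest class index, set E) as
# positive, so sensitivity is seizure recall. Multi-class metrics are
# unweighted one-vs-rest macro averages; the published tables report single
# values for 3-5-class tasks without defining the reduction, and the
# symmetric macro average is used here throughout.

#' Confusion matrix from true and predicted labels
#'
#' @param true,pred Integer class labels in `0 .. n_classes-1`.
#' @param n_classes Number of classes.
#' @return Object of class `confusion_matrix`: a K x K integer matrix,
#'   rows = true class, columns = predicted class.
#' @export
confusion_matrix <- function(true, pred, n_classes) {
  true <- as.integer(true)
  pred <- as.integer(pred)
  stopifnot(length(true) == length(pred),
            all(true >= 0), all(true < n_classes),
            all(pred >= 0), all(pred < n_classes))
  cm <- matrix(0L, n_classes, n_classes,
               dimnames = list(true = 0:(n_classes - 1),
                               pred = 0:(n_classes - 1)))
  for (i in seq_along(true)) {
    cm[true[i] + 1L, pred[i] + 1L] <- cm[true[i] + 1L, pred[i] + 1L] + 1L
  }
  structure(cm, class = c("confusion_matrix", "matrix"))
}

#' Accuracy, specificity, sensitivity and F1 from a confusion matrix
#'
#' For two classes the four quantities are computed from TP/TN/FP/FN with
#' the highest class index (the seizure class) as positive:
#' accuracy = (TP+TN)/(TP+TN+FP+FN), sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP), F1 = 2TP/(2TP+FP+FN). For K > 2 each metric is
#' computed one-vs-rest per class and macro-averaged (unweighted); accuracy
#' is then the usual multi-class trace(cm)/sum(cm). Zero-denominator
#' per-class metrics are defined as 0 with a warning.
#'
#' @param cm A `confusion_matrix` or plain K x K count matrix.
#' @return Named numeric vector (percent): `accuracy`, `specificity`,
#'   `sensitivity`, `f1`.
#' @export
metrics_from_confusion <- function(cm) {
  cm <- unclass(cm)
  stopifnot(is.matrix(cm), nrow(cm) == ncol(cm), nrow(cm) >= 2,
            all(cm >= 0))
  K <- nrow(cm)
  total <- sum(cm)
  if (total == 0) stop("metrics_from_confusion: empty confusion matrix",
                       call. = FALSE)

  per_class <- function(k) {
    tp <- cm[k, k]
    fn <- sum(cm[k, ]) - tp
    fp <- sum(cm[, k]) - tp
    tn <- total - tp - fn - fp
    safe <- function(num, den, what) {
      if (den == 0) {
        warning(sprintf("class %d: %s undefined (0/0), reported as 0",
                        k - 1L, what), call. = FALSE)
        return(0)
      }
      num / den
    }
    c(sensitivity = safe(tp, tp + fn, "sensitivity"),
      specificity = safe(tn, tn + fp, "specificity"),
      f1 = safe(2 * tp, 2 * tp + fp + fn, "F1"))
  }

  if (K == 2) {
    m <- per_class(2L)  # positive = highest class index (seizure)
    acc <- sum(diag(cm)) / total
    return(100 * c(accuracy = acc, specificity = m[["specificity"]],
                   sensitivity = m[["sensitivity"]], f1 = m[["f1"]]))
  }
  per <- vapply(seq_len(K), per_class, numeric(3))
  100 * c(accuracy = sum(diag(cm)) / total,
          specificity = mean(per["specificity", ]),
          sensitivity = mean(per["sensitivity", ]),
          f1 = mean(per["f1", ]))
}

#' Stratified k-fold split
#'
#' Partitions segment indices into `folds` disjoint, exhaustive test folds,
#' stratified by class (per-class fold sizes differ by at most 1), shuffled
#' deterministically by `seed`.
#'
#' @param dataset A `segmented_dataset`, or an integer label vector.
#' @param folds Number of folds (>= 2).
#' @param seed Integer seed.
#' @return List of `folds` elements, each `list(train = idx, test = idx)`
#'   (1-based indices).
#' @export
make_folds <- function(dataset, folds = 5L, seed = 1L) {
  labels <- if (inherits(dataset, "segmented_dataset")) dataset$labels
            else as.integer(dataset)
  folds <- as.integer(folds)
  stopifnot(folds >= 2)
  counts <- table(labels)
  if (any(counts < folds)) {
    stop(sprintf(
      "make_folds: class %s has %d segments, fewer than %d folds",
      names(counts)[which.min(counts)], min(counts), folds), call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))

  assignment <- integer(length(labels))
  for (cl in sort(unique(labels))) {
    idx <- sample(which(labels == cl))
    assignment[idx] <- rep_len(seq_len(folds), length(idx))
  }
  lapply(seq_len(folds), function(f) {
    list(train = which(assignment != f), test = which(assignment == f))
  })
}

#' Cross-validated training and evaluation of one configuration
#'
#' For each fold a fresh model is built and trained (categorical
#' cross-entropy, Adam) on the training folds, the held-out fold is
#' predicted by argmax, and the four metrics are computed from the fold's
#' confusion matrix. Fold-averaged values are the arithmetic means over
#' completed folds; folds whose training diverges are excluded and the
#' report is marked partial.
#'
#' @param dataset A `segmented_dataset`.
#' @param model_config A `model_config` (possibly [ablate()]d).
#' @param train_config A `train_config`.
#' @param seed Integer seed controlling the fold split, weight
#'   initialization and shuffling.
#' @param verbose Print per-fold progress.
#' @return Object of class `metrics_report`: `per_fold` (data frame),
#'   `mean` (named vector), `confusions` (list), `folds` (the index lists),
#'   `timing` (per-fold train/inference seconds, informational), `partial`.
#' @export
crossvalidate <- function(dataset, model_config, train_config, seed = 1L,
                          verbose = FALSE) {
  stopifnot(inherits(dataset, "segmented_dataset"),
            inherits(model_config, "model_config"),
            inherits(train_config, "train_config"))
  if (dataset$task$n_classes != model_config$n_classes) {
    stop("crossvalidate: dataset task and model n_classes disagree",
         call. = FALSE)
  }
  folds <- make_folds(dataset, train_config$folds, seed = seed)
  x <- dataset$segments
  y <- dataset$labels
  per_fold <- list()
  confusions <- list()
  timing <- list()
  failed <- integer(0)

  for (f in seq_along(folds)) {
    tr <- folds[[f]]$train
    te <- folds[[f]]$test
    model <- build_model(model_config, ncol(x),
                         seed = as.integer(seed) + 1000L * f)
    t0 <- proc.time()[["elapsed"]]
    model <- train_model(model, x[tr, , drop = FALSE], y[tr],
                         train = train_config,
                         seed = as.integer(seed) + 1000L * f + 1L)
    t1 <- proc.time()[["elapsed"]]
    if (isTRUE(model$diverged)) {
      warning(sprintf("fold %d: training diverged (non-finite loss); excluded",
                      f), call. = FALSE)
      failed <- c(failed, f)
      next
    }
    pred <- predict(model, x[te, , drop = FALSE], type = "class",
                    batch_size = train_config$batch_size)
    t2 <- proc.time()[["elapsed"]]
    cm <- confusion_matrix(y[te], pred, model_config$n_classes)
    confusions[[length(confusions) + 1L]] <- cm
    m <- metrics_from_confusion(cm)
    per_fold[[length(per_fold) + 1L]] <-
      data.frame(fold = f, accuracy = m[["accuracy"]],
                 specificity = m[["specificity"]],
                 sensitivity = m[["sensitivity"]], f1 = m[["f1"]],
                 n_train = length(tr), n_test = length(te))
    timing[[length(timing) + 1L]] <-
      c(fold = f, train_s = t1 - t0, infer_s = t2 - t1)
    if (verbose) {
      message(sprintf("fold %d/%d: accuracy %.2f%% (train %d / test %d)",
                      f, length(folds), m[["accuracy"]],
                      length(tr), length(te)))
    }
  }
  if (length(per_fold) == 0) {
    stop("crossvalidate: every fold failed", call. = FALSE)
  }
  pf <- do.call(rbind, per_fold)
  structure(
    list(per_fold = pf,
         mean = colMeans(pf[, c("accuracy", "specificity",
                                "sensitivity", "f1")]),
         confusions = confusions,
         folds = folds,
         timing = do.call(rbind, timing),
         partial = length(failed) > 0,
         failed_folds = failed,
         model_config = model_config,
         train_config = train_config,
         seed = as.integer(seed)),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %s study %d task %s%s%s\n",
              x$model_config$rnn_type, x$model_config$study,
              x$model_config$task,
              if (!is.null(x$model_config$ablated))
                sprintf(" [ablated: %s]", x$model_config$ablated) else "",
              if (x$partial) " (PARTIAL: some folds failed)" else ""))
  print(round(x$per_fold[, 1:5], 2), row.names = FALSE)
  cat(sprintf("fold means: accuracy %.2f%%  specificity %.2f%%  sensitivity %.2f%%  F1 %.2f%%\n",
              x$mean[["accuracy"]], x$mean[["specificity"]],
              x$mean[["sensitivity"]], x$mean[["f1"]]))
  invisible(x)
}

# resolve a data source into a record list:
#  - a directory path -> Bonn-layout tree read with load_set()
#  - a list(n_per_class=, n_points=, fs=, profiles=) -> synthetic dataset
#  - a list of eeg_record objects -> used as is
.resolve_records <- function(data_source, sets_needed, seed) {
  if (is.character(data_source) && length(data_source) == 1L) {
    recs <- list()
    for (s in sets_needed) recs <- c(recs, load_set(data_source, s))
    return(recs)
  }
  if (is.list(data_source) && length(data_source) > 0 &&
      inherits(data_source[[1]], "eeg_record")) {
    return(data_source)
  }
  if (is.list(data_source)) {
    args <- data_source
    n_per_class <- args$n_per_class %||% 100L
    n_points <- args$n_points %||% BONN_N_POINTS
    fs <- args$fs %||% BONN_FS
    profiles <- args$profiles %||% default_profiles()
    recs <- generate_dataset(n_per_class, n_points, fs, seed = seed,
                             profiles = profiles)
    return(recs[vapply(recs, function(r) r$set_id, character(1)) %in%
                  sets_needed])
  }
  stop("run_study: data_source must be a directory, a record list, or a synthetic spec list",
       call. = FALSE)
}

#' Run one complete study/task/RNN experiment
#'
#' Composes data loading (or surrogate generation), preprocessing and
#' segmentation for the study, configuration lookup and cross-validated
#' training/evaluation.
#'
#' @param study Study number 1-6.
#' @param task Task name.
#' @param rnn_type `"BiLSTM"` or `"BiGRU"`.
#' @param data_source Bonn-layout directory, list of [eeg_record()]s, or a
#'   synthetic spec `list(n_per_class =, n_points =, fs =, profiles =)`.
#' @param seed Integer seed (generation, folds, initialization, shuffling).
#' @param epochs Optional override of the published epoch count (the
#'   published value can require long runs).
#' @param verbose Print per-fold progress.
#' @return A `metrics_report`.
#' @export
run_study <- function(study, task, rnn_type = "BiLSTM",
                      data_source = list(n_per_class = 100L),
                      seed = 1L, epochs = NULL, verbose = FALSE) {
  cfg <- get_config(study, task, rnn_type)
  if (!is.null(epochs)) cfg$train$epochs <- as.integer(epochs)
  task_s <- task_spec(task)
  recs <- .resolve_records(data_source, names(task_s$class_map), seed)
  labelled <- make_task(recs, task)
  dataset <- build_study_dataset(labelled, study)
  crossvalidate(dataset, cfg$model, cfg$train, seed = seed,
                verbose = verbose)
}

#' Run one ablation experiment
#'
#' As [run_study()] but with all conv stages (`drop = "conv"`) or all
#' bidirectional recurrent stages (`drop = "rnn"`) removed before
#' retraining.
#'
#' @inheritParams run_study
#' @param drop `"conv"` or `"rnn"`.
#' @return A `metrics_report` whose config records the ablation kind.
#' @export
run_ablation <- function(study, task, drop, rnn_type = "BiLSTM",
                         data_source = list(n_per_class = 100L),
                         seed = 1L, epochs = NULL, verbose = FALSE) {
  cfg <- get_config(study, task, rnn_type)
  if (!is.null(epochs)) cfg$train$epochs <- as.integer(epochs)
  cfg$model <- ablate(cfg$model, drop)
  task_s <- task_spec(task)
  recs <- .resolve_records(data_source, names(task_s$class_map), seed)
  labelled <- make_task(recs, task)
  dataset <- build_study_dataset(labelled, study)
  crossvalidate(dataset, cfg$model, cfg$train, seed = seed,
                verbose = verbose)
}

#' Write a metrics report as a tabular file
#'
#' One row per fold plus a mean row: study, task, rnn, fold, the four
#' metrics, and wall-clock training/inference seconds (informational).
#'
#' @param report A `metrics_report`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "metrics_report"))
  pf <- report$per_fold
  tm <- as.data.frame(report$timing)
  rows <- data.frame(
    study = report$model_config$study, task = report$model_config$task,
    rnn = report$model_config$rnn_type,
    ablated = if (is.null(report$model_config$ablated)) ""
              else report$model_config$ablated,
    fold = as.character(pf$fold),
    accuracy = pf$accuracy, specificity = pf$specificity,
    sensitivity = pf$sensitivity, f1 = pf$f1,
    train_s = tm$train_s[match(pf$fold, tm$fold)],
    infer_s = tm$infer_s[match(pf$fold, tm$fold)])
  mean_row <- rows[1, ]
  mean_row$fold <- "mean"
  mean_row[, c("accuracy", "specificity", "sensitivity", "f1")] <-
    as.list(report$mean)
  mean_row$train_s <- mean(tm$train_s)
  mean_row$infer_s <- mean(tm$infer_s)
  utils::write.table(rbind(rows, mean_row), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
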