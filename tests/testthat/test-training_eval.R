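test_that("the binary worked example evaluates exactly", {
  # seizure class (index 1) positive: TP=3, TN=4, FP=1, FN=2
  cm <- matrix(c(4L, 1L,
                 2L, 3L), 2, 2, byrow = TRUE)
  m <- metrics_from_confusion(cm)
  expect_equal(m[["accuracy"]], 70)
  expect_equal(m[["sensitivity"]], 60)
  expect_equal(m[["specificity"]], 80)
  expect_equal(m[["f1"]], 66.6667, tolerance = 1e-4)
})

test_that("perfect predictions score 100 on all four metrics", {
  for (K in 2:5) {
    cm <- diag(5L, K)
    expect_equal(unname(metrics_from_confusion(cm)), rep(100, 4))
  }
})

test_that("metrics agree with a brute-force pair-enumeration oracle", {
  set.seed(77)
  for (i in 1:1000) {
    K <- sample(2:5, 1)
    cm <- random_cm(K)
    # zero-denominator classes are defined as 0 in both implementations
    got <- suppressWarnings(metrics_from_confusion(cm))
    want <- oracle_metrics(cm)
    expect_equal(unname(got), unname(want), tolerance = 1e-12)
  }
})

test_that("accuracy equals trace over total and macro averages are
           permutation-invariant", {
  set.seed(5)
  for (i in 1:50) {
    K <- sample(3:5, 1)
    cm <- random_cm(K)
    m <- suppressWarnings(metrics_from_confusion(cm))
    expect_equal(m[["accuracy"]], 100 * sum(diag(cm)) / sum(cm))
    perm <- sample(K)
    m2 <- suppressWarnings(metrics_from_confusion(cm[perm, perm]))
    expect_equal(m2[["accuracy"]], m[["accuracy"]])
    expect_equal(m2[["sensitivity"]], m[["sensitivity"]], tolerance = 1e-12)
    expect_equal(m2[["specificity"]], m[["specificity"]], tolerance = 1e-12)
    expect_equal(m2[["f1"]], m[["f1"]], tolerance = 1e-12)
  }
})

test_that("degenerate confusion matrices warn and report 0", {
  cm <- matrix(c(0L, 0L, 5L, 5L), 2, 2, byrow = TRUE)  # no true negatives
  expect_warning(m <- metrics_from_confusion(cm), "undefined")
  expect_equal(m[["specificity"]], 0)
})

test_that("confusion_matrix counts true/predicted pairs", {
  cm <- confusion_matrix(c(0, 0, 1, 1, 2), c(0, 1, 1, 1, 0), 3L)
  expect_equal(sum(cm), 5L)
  expect_equal(unclass(cm)[1, ], c(`0` = 1L, `1` = 1L, `2` = 0L))
  expect_equal(unclass(cm)[2, 2], 2L)
  expect_error(confusion_matrix(c(0, 3), c(0, 0), 3L))
})

test_that("stratified folds partition the data with the published sizes", {
  # 200 full-length binary signals: 160 train / 40 test per fold
  y200 <- rep(0:1, each = 100)
  folds <- make_folds(y200, 5L, seed = 1L)
  for (f in folds) {
    expect_length(f$test, 40L)
    expect_length(f$train, 160L)
    expect_length(intersect(f$train, f$test), 0L)
    expect_equal(as.vector(table(y200[f$test])), c(20L, 20L))
  }
  expect_setequal(unlist(lapply(folds, `[[`, "test")), seq_along(y200))

  # 1,000 segments: 800/200; 500 signals: 400/100
  y1000 <- rep(0:2, c(400, 400, 200))
  f1000 <- make_folds(y1000, 5L, seed = 2L)
  expect_equal(unique(vapply(f1000, function(f) length(f$test), 1L)), 200L)
  expect_equal(unique(vapply(f1000, function(f) length(f$train), 1L)), 800L)

  y500 <- rep(0:4, each = 100)
  f500 <- make_folds(y500, 5L, seed = 3L)
  expect_equal(unique(vapply(f500, function(f) length(f$test), 1L)), 100L)

  # per-class fold sizes differ by at most one even when counts do not divide
  y23 <- rep(0:1, c(23, 31))
  f23 <- make_folds(y23, 5L, seed = 4L)
  per_fold <- vapply(f23, function(f) sum(y23[f$test] == 0), 1L)
  expect_lte(diff(range(per_fold)), 1L)

  expect_identical(make_folds(y200, 5L, seed = 9L),
                   make_folds(y200, 5L, seed = 9L))
  expect_false(identical(make_folds(y200, 5L, seed = 9L),
                         make_folds(y200, 5L, seed = 10L)))
  expect_error(make_folds(rep(0:1, c(3, 100)), 5L), "fewer than")
})

test_that("cross-validation trains, evaluates and averages over folds", {
  recs <- tiny_records(n_per_class = 6L, n_points = 400L, seed = 21L)
  lab <- make_task(records_of(recs, c("A", "E")), "A-E")
  ds <- build_study_dataset(lab, 5)  # 400/178 -> 2 segments per record
  cfg <- tiny_config("BiLSTM")
  train <- structure(list(epochs = 4L, batch_size = 8L,
                          learning_rate = 0.005, folds = 3L),
                     class = "train_config")
  # rebuild the tiny config at the dataset's segment length
  rep <- crossvalidate(ds, cfg, train, seed = 6L)
  expect_s3_class(rep, "metrics_report")
  expect_equal(nrow(rep$per_fold), 3L)
  expect_false(rep$partial)
  expect_equal(unname(rep$mean),
               unname(colMeans(rep$per_fold[, c("accuracy", "specificity",
                                                "sensitivity", "f1")])))
  expect_length(rep$confusions, 3L)
  expect_true(all(vapply(rep$confusions, sum, 1) ==
                    vapply(rep$folds, function(f) length(f$test), 1L)))
  expect_true(all(rep$per_fold$accuracy >= 0 & rep$per_fold$accuracy <= 100))

  # shared-split contract: equal seeds give identical folds across RNN types
  rep2 <- crossvalidate(ds, tiny_config("BiGRU"), train, seed = 6L)
  expect_identical(rep$folds, rep2$folds)

  # report serialization: one row per fold plus a mean row
  path <- withr::local_tempfile(fileext = ".tsv")
  write_report(rep, path)
  tab <- read.delim(path)
  expect_equal(nrow(tab), 4L)
  expect_equal(tab$fold[4], "mean")
  expect_equal(tab$accuracy[4], rep$mean[["accuracy"]], tolerance = 1e-6)
})

test_that("run_study composes generation, preprocessing and evaluation", {
  rep <- run_study(5, "A-E", "BiLSTM",
                   data_source = list(n_per_class = 10L, n_points = 400L),
                   seed = 33L, epochs = 3L)
  expect_s3_class(rep, "metrics_report")
  expect_equal(nrow(rep$per_fold), 5L)
  # 20 records x 2 segments, stratified 5-fold: 8 test segments per fold
  expect_equal(unique(rep$per_fold$n_test), 8L)
  expect_error(run_study(7, "A-E"), "study")
})

test_that("run_ablation trains the reduced architecture", {
  rep <- run_ablation(5, "A-E", drop = "rnn",
                      data_source = list(n_per_class = 8L, n_points = 400L),
                      seed = 13L, epochs = 3L)
  expect_equal(rep$model_config$ablated, "rnn")
  expect_error(run_ablation(5, "A-E", drop = "flatten",
                            data_source = list(n_per_class = 8L,
                                               n_points = 400L)),
               "conv.*rnn")
})
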