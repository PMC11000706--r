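# expected number of Conv->Bi-RNN->AvgPool units per study and task,
# mirroring the published architecture table
UNIT_COUNTS <- list(
  `1` = c("A-E" = 2, "B-E" = 2, "AB-CD-E" = 2, "AB-C-D-E" = 3, "A-B-C-D-E" = 3),
  `2` = c("A-E" = 2, "B-E" = 2, "AB-CD-E" = 3, "AB-C-D-E" = 3, "A-B-C-D-E" = 3),
  `3` = c("A-E" = 3, "B-E" = 3, "AB-CD-E" = 3, "AB-C-D-E" = 4, "A-B-C-D-E" = 3),
  `4` = c("A-E" = 2, "B-E" = 3, "AB-CD-E" = 3, "AB-C-D-E" = 4, "A-B-C-D-E" = 3),
  `5` = c("A-E" = 3, "B-E" = 3, "AB-CD-E" = 2, "AB-C-D-E" = 2, "A-B-C-D-E" = 2),
  `6` = c("A-E" = 1, "B-E" = 1, "AB-CD-E" = 3, "AB-C-D-E" = 2, "A-B-C-D-E" = 2)
)

test_that("every study/task/RNN combination resolves with the right unit count", {
  for (study in 1:6) {
    for (task in task_names()) {
      for (rnn in c("BiLSTM", "BiGRU")) {
        cfg <- get_config(study, task, rnn, quiet = TRUE)
        expect_length(cfg$model$units, UNIT_COUNTS[[as.character(study)]][[task]])
        expect_equal(cfg$model$rnn_type, rnn)
        expect_equal(cfg$model$n_classes, task_spec(task)$n_classes)
        expect_equal(cfg$train$batch_size, 64L)
        expect_equal(cfg$train$folds, 5L)
        expect_gte(cfg$train$epochs, 1L)
      }
    }
  }
})

test_that("resolved configurations carry the published layer widths", {
  c1 <- get_config(1, "A-E", "BiLSTM", quiet = TRUE)
  expect_equal(vapply(c1$model$units, `[[`, integer(1), "conv_filters"),
               c(32L, 16L))
  expect_equal(vapply(c1$model$units, `[[`, integer(1), "rnn_units"),
               c(16L, 8L))
  expect_equal(c1$model$units[[1]]$kernel_size, 2L)
  expect_equal(c1$model$dense_units, 100L)
  expect_equal(c1$train$epochs, 50L)

  c3 <- get_config(3, "AB-C-D-E", "BiLSTM", quiet = TRUE)
  expect_equal(vapply(c3$model$units, `[[`, integer(1), "conv_filters"),
               c(256L, 128L, 64L, 32L))
  expect_equal(vapply(c3$model$units, `[[`, integer(1), "rnn_units"),
               c(32L, 32L, 16L, 8L))

  # missing published dense width: fallback filled in, flagged, warned
  expect_warning(c4 <- get_config(4, "A-B-C-D-E", "BiLSTM"),
                 "fallback")
  expect_true("dense" %in% c4$model$incomplete)
  expect_equal(c4$model$dense_units, 100L)

  # single-unit filtered 1 s binary models have no dropout stage
  c6 <- get_config(6, "A-E", "BiGRU", quiet = TRUE)
  expect_null(c6$model$dropout_rate)
  expect_equal(c6$model$dense_units, c(100L, 10L))

  # kernel-size exceptions
  expect_equal(get_config(2, "AB-C-D-E", quiet = TRUE)$model$units[[1]]$kernel_size, 4L)
  expect_equal(get_config(5, "A-B-C-D-E", quiet = TRUE)$model$units[[1]]$kernel_size, 8L)

  expect_error(get_config(7, "A-E"), "study")
  expect_error(get_config(1, "A-D"), "unknown task")
  expect_error(get_config(1, "A-E", "transformer"), "rnn_type")
})

test_that("the builder emits the unit stack in order with correct shapes", {
  cfg <- get_config(1, "A-E", "BiLSTM", quiet = TRUE)
  m <- build_model(cfg$model, 4097L, seed = 1L)
  expect_equal(layer_types(m),
               c("conv", "bilstm", "avgpool", "dropout",
                 "conv", "bilstm", "avgpool",
                 "flatten", "dense", "output"))
  # valid padding: 4097 -> 4096; pool: 4096 -> 2048 -> conv 2047 -> pool 1023
  lens <- vapply(m$shapes, `[[`, numeric(1), "len")
  expect_equal(lens[1:7], c(4096, 4096, 2048, 2048, 2047, 2047, 1023))
  expect_equal(m$shapes[[2]][["channels"]], 32)  # 16 units x 2 directions
  expect_equal(m$shapes[[8]][["channels"]], 16 * 1023)  # flatten width
  expect_gt(m$n_params, 0)

  # parameter count is reproducible and matches the allocated weights
  m2 <- build_model(cfg$model, 4097L, seed = 99L)
  expect_equal(m2$n_params, m$n_params)
  n_alloc <- sum(unlist(lapply(m$params, function(p) vapply(p, length, 1))))
  expect_equal(n_alloc, m$n_params)

  # identical seeds give identical weights; different seeds differ
  m3 <- build_model(cfg$model, 4097L, seed = 1L)
  expect_identical(m$params, m3$params)
  expect_false(identical(m$params, m2$params))
})

test_that("networks output a probability simplex for random inputs", {
  set.seed(31)
  for (spec in list(c(5, "A-B-C-D-E", "BiLSTM"), c(6, "AB-CD-E", "BiGRU"),
                    c(6, "A-E", "BiLSTM"))) {
    cfg <- get_config(as.integer(spec[1]), spec[2], spec[3], quiet = TRUE)
    m <- build_model(cfg$model, 178L, seed = 4L)
    x <- matrix(rnorm(3 * 178), 3, 178)
    p <- predict(m, x)
    expect_equal(dim(p), c(3L, cfg$model$n_classes))
    expect_true(all(p >= 0))
    expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-5)
  }
})

test_that("ablation removes exactly the conv or recurrent stages", {
  cfg <- get_config(1, "A-E", "BiLSTM", quiet = TRUE)
  full <- build_model(cfg$model, 4097L, seed = 1L)

  no_conv <- build_model(ablate(cfg$model, "conv"), 4097L, seed = 1L)
  tns <- layer_types(no_conv)
  expect_equal(sum(tns == "conv"), 0L)
  expect_equal(sum(tns == "bilstm"), 2L)
  expect_equal(sum(tns == "avgpool"), 2L)
  expect_lt(no_conv$n_params, full$n_params)

  no_rnn <- build_model(ablate(cfg$model, "rnn"), 4097L, seed = 1L)
  tns <- layer_types(no_rnn)
  expect_equal(sum(tns == "conv"), 2L)
  expect_equal(sum(tns == "bilstm"), 0L)
  expect_lt(no_rnn$n_params, full$n_params)

  # dense stack and dropout unchanged by ablation
  expect_equal(ablate(cfg$model, "conv")$dense_units, cfg$model$dense_units)
  expect_equal(ablate(cfg$model, "conv")$dropout_rate, cfg$model$dropout_rate)

  expect_error(ablate(cfg$model, "pool"), "conv.*rnn")
  expect_error(ablate(cfg$model, "flatten"), "conv.*rnn")
})

test_that("degenerate inputs are rejected at construction", {
  cfg <- get_config(3, "AB-C-D-E", "BiLSTM", quiet = TRUE)  # 4 units
  expect_error(build_model(cfg$model, 8L), "collapses the temporal axis")
  empty <- tiny_config()
  empty$units <- list()
  expect_error(build_model(empty, 100L), "no units")
})

test_that("a user-supplied registry file is schema-validated", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("defaults: {batch_size: 64, learning_rate: 0.001, pool_size: 2,",
               "  conv_stride: 1, conv_padding: valid, folds: 5}",
               "configs:",
               "  - {study: 9, task: A-E, units: [[4, 4]], kernel: 2,",
               "     dense: [10], dropout: 0.1, epochs: 5, incomplete: []}"),
             path)
  expect_error(load_registry(path), "invalid entry")
})
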