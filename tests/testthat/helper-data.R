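# Shared fixtures, built in code at test time.

# small labelled record set covering all five classes
tiny_records <- function(n_per_class = 2L, n_points = 600L, seed = 42L) {
  generate_dataset(n_per_class, n_points = n_points, seed = seed)
}

# records restricted to given sets
records_of <- function(records, sets) {
  records[vapply(records, function(r) r$set_id, character(1)) %in% sets]
}

# a small custom configuration (not from the registry) for engine tests
tiny_config <- function(rnn_type = "BiLSTM", n_classes = 2L,
                        dropout = NULL, units = NULL) {
  if (is.null(units)) {
    units <- list(
      list(conv_filters = 4L, kernel_size = 2L, rnn_units = 3L,
           rnn_type = rnn_type),
      list(conv_filters = 3L, kernel_size = 2L, rnn_units = 2L,
           rnn_type = rnn_type))
  }
  structure(
    list(study = 1L, task = "A-E", rnn_type = rnn_type, units = units,
         pool_size = 2L, dropout_rate = dropout, dense_units = 5L,
         n_classes = as.integer(n_classes), conv_stride = 1L,
         conv_padding = "valid", incomplete = character(0)),
    class = "model_config")
}

# brute-force metric oracle: expand the confusion matrix into (true, pred)
# pairs and count TP/TN/FP/FN per class by enumeration
oracle_metrics <- function(cm) {
  K <- nrow(cm)
  pairs <- do.call(rbind, lapply(seq_len(K), function(i)
    do.call(rbind, lapply(seq_len(K), function(j)
      if (cm[i, j] > 0)
        matrix(rep(c(i - 1L, j - 1L), cm[i, j]), ncol = 2, byrow = TRUE)))))
  per <- sapply(seq_len(K) - 1L, function(k) {
    tp <- sum(pairs[, 1] == k & pairs[, 2] == k)
    fn <- sum(pairs[, 1] == k & pairs[, 2] != k)
    fp <- sum(pairs[, 1] != k & pairs[, 2] == k)
    tn <- sum(pairs[, 1] != k & pairs[, 2] != k)
    c(sens = if (tp + fn > 0) tp / (tp + fn) else 0,
      spec = if (tn + fp > 0) tn / (tn + fp) else 0,
      f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0)
  })
  acc <- sum(diag(cm)) / sum(cm)
  if (K == 2) {
    100 * c(accuracy = acc, specificity = per["spec", 2],
            sensitivity = per["sens", 2], f1 = per["f1", 2])
  } else {
    100 * c(accuracy = acc, specificity = mean(per["spec", ]),
            sensitivity = mean(per["sens", ]), f1 = mean(per["f1", ]))
  }
}

random_cm <- function(K, max_count = 30L) {
  m <- matrix(sample(0:max_count, K * K, replace = TRUE), K, K)
  if (sum(m) == 0) m[1, 1] <- 1L
  m
}
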