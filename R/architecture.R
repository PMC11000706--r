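# Declarative model configurations and the network builder.
#
# Every network is a stack of 1-4 feature-extraction units
# (Conv1D -> bidirectional recurrent layer -> average pooling), with a
# dropout stage between consecutive units, followed by Flatten, a stack of
# ReLU dense layers and a softmax output. The published unit widths, kernel
# sizes, dense stacks, dropout rates and epoch counts are shipped as a YAML
# registry (inst/extdata/model_registry.yaml), one entry per study x task,
# shared between the Bi-LSTM and Bi-GRU variants.

.registry_env <- new.env(parent = emptyenv())

.normalize_rnn_type <- function(rnn_type) {
  key <- tolower(gsub("[-_ ]", "", rnn_type))
  if (key %in% c("bilstm", "lstm")) return("BiLSTM")
  if (key %in% c("bigru", "gru")) return("BiGRU")
  stop(sprintf("unknown rnn_type '%s' (use BiLSTM or BiGRU)", rnn_type),
       call. = FALSE)
}

.validate_registry <- function(reg) {
  stopifnot(is.list(reg), !is.null(reg$configs), !is.null(reg$defaults))
  for (e in reg$configs) {
    ok <- is.numeric(e$study) && e$study %in% 1:6 &&
      is.character(e$task) &&
      length(e$units) >= 1 && length(e$units) <= 4 &&
      all(vapply(e$units, function(u)
        length(u) == 2 && all(u >= 1), logical(1))) &&
      e$kernel >= 1 &&
      all(unlist(e$dense) >= 1) &&
      (is.null(e$dropout) || (e$dropout >= 0 && e$dropout < 1)) &&
      e$epochs >= 1
    if (!ok) {
      stop(sprintf("model registry: invalid entry for study %s task %s",
                   e$study, e$task), call. = FALSE)
    }
    normalize_task_name(e$task)  # errors on unknown task
  }
  tasks <- vapply(reg$configs, function(e)
    sprintf("%d/%s", e$study, normalize_task_name(e$task)), character(1))
  if (anyDuplicated(tasks)) {
    stop("model registry: duplicated study/task entry", call. = FALSE)
  }
  invisible(reg)
}

#' Load the model-configuration registry
#'
#' @param path Path to a registry YAML; defaults to the registry shipped
#'   with the package. The registry is schema-validated on load.
#' @return The registry list (fields `defaults` and `configs`).
#' @export
load_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "model_registry.yaml", package = "seizunit")
    if (!is.null(.registry_env$default)) return(.registry_env$default)
    reg <- .validate_registry(yaml::read_yaml(path))
    .registry_env$default <- reg
    return(reg)
  }
  .validate_registry(yaml::read_yaml(path))
}

#' Resolve the published configuration for one study/task/RNN combination
#'
#' Combinations whose published description omits a value (some dense
#' widths, the Study 1 dropout rate, some epoch counts) are returned with
#' the documented fallback filled in, flagged in `$model$incomplete`, with
#' a warning.
#'
#' @param study Study number 1-6.
#' @param task Task name (see [task_spec()]).
#' @param rnn_type `"BiLSTM"` or `"BiGRU"` (case/format-insensitive).
#' @param registry Optional registry list from [load_registry()].
#' @param quiet Suppress the incomplete-entry warning.
#' @return List with `model` (class `model_config`) and `train` (class
#'   `train_config`).
#' @export
get_config <- function(study, task, rnn_type = "BiLSTM", registry = NULL,
                       quiet = FALSE) {
  if (is.null(registry)) registry <- load_registry()
  rnn_type <- .normalize_rnn_type(rnn_type)
  task <- normalize_task_name(task)
  if (!study %in% 1:6) {
    stop(sprintf("get_config: unknown study %s", paste(study)), call. = FALSE)
  }
  hit <- NULL
  for (e in registry$configs) {
    if (e$study == study && normalize_task_name(e$task) == task) {
      hit <- e
      break
    }
  }
  if (is.null(hit)) {
    stop(sprintf("get_config: no registry entry for study %d task %s",
                 study, task), call. = FALSE)
  }
  d <- registry$defaults
  incomplete <- as.character(unlist(hit$incomplete))
  if (length(incomplete) > 0 && !quiet) {
    warning(sprintf(
      "config %d/%s: published value missing for %s; using documented fallback",
      study, task, paste(incomplete, collapse = ", ")), call. = FALSE)
  }
  units <- lapply(hit$units, function(u) {
    list(conv_filters = as.integer(u[[1]]), kernel_size = as.integer(hit$kernel),
         rnn_units = as.integer(u[[2]]), rnn_type = rnn_type)
  })
  model <- structure(
    list(study = as.integer(study), task = task, rnn_type = rnn_type,
         units = units,
         pool_size = as.integer(d$pool_size),
         dropout_rate = if (is.null(hit$dropout)) NULL else as.numeric(hit$dropout),
         dense_units = as.integer(unlist(hit$dense)),
         n_classes = task_spec(task)$n_classes,
         conv_stride = as.integer(d$conv_stride),
         conv_padding = d$conv_padding,
         incomplete = incomplete),
    class = "model_config")
  train <- structure(
    list(epochs = as.integer(hit$epochs),
         batch_size = as.integer(d$batch_size),
         learning_rate = as.numeric(d$learning_rate),
         folds = as.integer(d$folds)),
    class = "train_config")
  list(model = model, train = train)
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf("<model_config> study %d, task %s, %s, %d classes\n",
              x$study, x$task, x$rnn_type, x$n_classes))
  for (i in seq_along(x$units)) {
    u <- x$units[[i]]
    cat(sprintf("  unit %d: Conv1D(%d, k=%d) -> %s(%d/dir) -> AvgPool(%d)\n",
                i, u$conv_filters, u$kernel_size, u$rnn_type, u$rnn_units,
                x$pool_size))
  }
  cat(sprintf("  dropout between units: %s\n",
              if (is.null(x$dropout_rate)) "none" else x$dropout_rate))
  cat(sprintf("  dense: %s -> softmax(%d)\n",
              paste(x$dense_units, collapse = ", "), x$n_classes))
  if (length(x$incomplete)) {
    cat(sprintf("  [incomplete: fallback used for %s]\n",
                paste(x$incomplete, collapse = ", ")))
  }
  invisible(x)
}

#' Remove all conv or all recurrent stages from a configuration
#'
#' The ablation protocol retrains networks with every 1D-conv stage removed
#' (`drop = "conv"`: units become Bi-RNN -> AvgPool) or every bidirectional
#' recurrent stage removed (`drop = "rnn"`: units become Conv1D -> AvgPool).
#' Dense stack, dropout and training settings are unchanged.
#'
#' @param config A `model_config`.
#' @param drop `"conv"` or `"rnn"`.
#' @return The ablated `model_config` (field `ablated` records the kind).
#' @export
ablate <- function(config, drop) {
  stopifnot(inherits(config, "model_config"))
  if (length(drop) != 1 || !drop %in% c("conv", "rnn")) {
    stop("ablate: drop must be \"conv\" or \"rnn\"", call. = FALSE)
  }
  config$ablated <- drop
  config
}

# engine layer list + shape trace for a configuration at a given input length
.plan_layers <- function(config, input_length) {
  stopifnot(inherits(config, "model_config"))
  drop <- if (is.null(config$ablated)) "" else config$ablated
  layers <- list()
  shapes <- list()
  ch <- 1L
  len <- as.integer(input_length)
  n_units <- length(config$units)
  if (n_units == 0) stop("build_model: configuration has no units", call. = FALSE)
  add <- function(l, ch, len) {
    layers[[length(layers) + 1L]] <<- l
    shapes[[length(shapes) + 1L]] <<- c(channels = ch, len = len)
  }
  for (i in seq_len(n_units)) {
    u <- config$units[[i]]
    if (drop != "conv") {
      new_len <- len - u$kernel_size + 1L
      if (new_len < 1) {
        stop(sprintf(
          "build_model: conv of unit %d collapses the temporal axis (%d -> %d)",
          i, len, new_len), call. = FALSE)
      }
      add(list(type = "conv", in_ch = ch, filters = u$conv_filters,
               kernel = u$kernel_size), u$conv_filters, new_len)
      ch <- u$conv_filters
      len <- new_len
    }
    if (drop != "rnn") {
      type <- if (u$rnn_type == "BiLSTM") "bilstm" else "bigru"
      add(list(type = type, in_ch = ch, units = u$rnn_units),
          2L * u$rnn_units, len)
      ch <- 2L * u$rnn_units
    }
    new_len <- len %/% config$pool_size
    if (new_len < 1) {
      stop(sprintf(
        "build_model: pooling of unit %d collapses the temporal axis (%d -> 0)",
        i, len), call. = FALSE)
    }
    add(list(type = "avgpool", pool = config$pool_size), ch, new_len)
    len <- new_len
    if (i < n_units && !is.null(config$dropout_rate)) {
      add(list(type = "dropout", rate = config$dropout_rate), ch, len)
    }
  }
  add(list(type = "flatten"), ch * len, 1L)
  dim_in <- ch * len
  for (d in config$dense_units) {
    add(list(type = "dense", in_dim = dim_in, units = as.integer(d)), d, 1L)
    dim_in <- as.integer(d)
  }
  add(list(type = "output", in_dim = dim_in, units = config$n_classes),
      config$n_classes, 1L)
  list(layers = layers, shapes = shapes)
}

#' Number of trainable parameters implied by a layer plan
#' @noRd
.count_params <- function(layers) {
  total <- 0
  for (l in layers) {
    total <- total + switch(
      l$type,
      conv = (l$in_ch * l$kernel + 1) * l$filters,
      bilstm = 2 * (4 * l$units * (l$in_ch + l$units + 1)),
      bigru = 2 * (3 * l$units * (l$in_ch + l$units + 1)),
      dense = (l$in_dim + 1) * l$units,
      output = (l$in_dim + 1) * l$units,
      0)
  }
  total
}

#' Instantiate a network from a configuration
#'
#' Builds the layer stack for `config` at the given input length and
#' initializes its weights (uniform Glorot; LSTM forget-gate biases 1).
#'
#' @param config A `model_config` from [get_config()] (possibly [ablate()]d).
#' @param input_length Samples per input segment.
#' @param seed Integer seed for weight initialization.
#' @return Object of class `seiz_model` with fields `config`, `layers`,
#'   `shapes`, `params`, `n_params`, `input_length`.
#' @export
build_model <- function(config, input_length, seed = 1L) {
  plan <- .plan_layers(config, input_length)
  params <- cpp_init_params(plan$layers, as.integer(seed))
  structure(
    list(config = config, layers = plan$layers, shapes = plan$shapes,
         params = params, n_params = .count_params(plan$layers),
         input_length = as.integer(input_length), trained = FALSE,
         loss_history = numeric(0)),
    class = "seiz_model")
}

#' @export
print.seiz_model <- function(x, ...) {
  cat(sprintf("<seiz_model> %s study %d task %s, input length %d, %s params%s\n",
              x$config$rnn_type, x$config$study, x$config$task,
              x$input_length, format(x$n_params, big.mark = ","),
              if (x$trained) " (trained)" else ""))
  for (i in seq_along(x$layers)) {
    l <- x$layers[[i]]
    desc <- switch(l$type,
      conv = sprintf("Conv1D(%d, k=%d)", l$filters, l$kernel),
      bilstm = sprintf("BiLSTM(%d/dir)", l$units),
      bigru = sprintf("BiGRU(%d/dir)", l$units),
      avgpool = sprintf("AvgPool(%d)", l$pool),
      dropout = sprintf("Dropout(%.2f)", l$rate),
      flatten = "Flatten",
      dense = sprintf("Dense(%d, relu)", l$units),
      output = sprintf("Dense(%d, softmax)", l$units))
    s <- x$shapes[[i]]
    cat(sprintf("  %-22s -> (%d x %d)\n", desc, s["channels"], s["len"]))
  }
  invisible(x)
}

#' Summarize a model's layer types
#'
#' @param model A `seiz_model`.
#' @return Character vector of layer types in order.
#' @export
layer_types <- function(model) {
  vapply(model$layers, function(l) l$type, character(1))
}

#' Train a model on a segment matrix
#'
#' Categorical cross-entropy minimized with Adam; data shuffled each epoch.
#'
#' @param model A `seiz_model`.
#' @param x Numeric matrix, one segment per row (`input_length` columns).
#' @param y Integer class labels in `0 .. n_classes-1`.
#' @param train A `train_config` (from [get_config()]), or NULL to pass
#'   `epochs` etc. directly.
#' @param epochs,batch_size,learning_rate Used when `train` is NULL.
#' @param seed Integer seed for shuffling and dropout.
#' @param verbose Print per-epoch loss.
#' @return The trained `seiz_model` (fields `params`, `loss_history`,
#'   `diverged` updated).
#' @export
train_model <- function(model, x, y, train = NULL, epochs = 10L,
                        batch_size = 64L, learning_rate = 0.001,
                        seed = 1L, verbose = FALSE) {
  stopifnot(inherits(model, "seiz_model"), is.matrix(x))
  if (!is.null(train)) {
    stopifnot(inherits(train, "train_config"))
    epochs <- train$epochs
    batch_size <- train$batch_size
    learning_rate <- train$learning_rate
  }
  if (ncol(x) != model$input_length) {
    stop(sprintf("train_model: segments have %d samples, model expects %d",
                 ncol(x), model$input_length), call. = FALSE)
  }
  y <- as.integer(y)
  stopifnot(length(y) == nrow(x), all(y >= 0),
            all(y < model$config$n_classes))
  fit <- cpp_train(model$layers, model$params, x, y,
                   model$config$n_classes, as.integer(epochs),
                   as.integer(batch_size), learning_rate,
                   as.integer(seed), verbose)
  model$params <- fit$params
  model$loss_history <- c(model$loss_history, as.numeric(fit$loss))
  model$diverged <- isTRUE(fit$diverged)
  model$trained <- TRUE
  model
}

#' Class-probability predictions
#'
#' @param object A `seiz_model`.
#' @param x Segment matrix (rows are segments).
#' @param type `"prob"` for the softmax matrix, `"class"` for argmax labels
#'   (ties broken toward the lowest class index).
#' @param batch_size Forward-pass batch size.
#' @param ... Unused.
#' @return Probability matrix or integer class vector.
#' @export
predict.seiz_model <- function(object, x, type = c("prob", "class"),
                               batch_size = 64L, ...) {
  type <- match.arg(type)
  stopifnot(is.matrix(x), ncol(x) == object$input_length)
  probs <- cpp_predict(object$layers, object$params, x,
                       as.integer(batch_size))
  if (type == "prob") return(probs)
  max.col(probs, ties.method = "first") - 1L
}
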