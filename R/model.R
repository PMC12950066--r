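# 1D CNN for window classification: configuration, construction, training,
# prediction. The numerical engine lives in src/cnn.cpp.

#' CNN hyperparameter configuration
#'
#' Architecture: `Conv1D(n_filters, kernel_len)` -> ReLU -> Dropout ->
#' `Conv1D(n_filters, kernel_len)` -> ReLU -> Dropout ->
#' `MaxPool(pool_len)` -> Dropout -> Flatten -> `Dense(dense_units)` -> ReLU
#' -> `Dense(2)` -> Softmax, trained with Adam on cross-entropy in
#' mini-batches, with early stopping on validation loss (best weights
#' restored).
#'
#' @param n_channels 3 (acceleration only) or 6 (acceleration + gyroscope).
#' @param window_len window length in samples (default 200).
#' @param n_filters filters per convolutional layer (default 64).
#' @param kernel_len odd convolution kernel length in samples (default 9,
#'   about 0.09 s at 100 Hz).
#' @param pool_len max-pooling width (default 2).
#' @param dense_units width of the fully connected layer (default 64).
#' @param dropout_rate dropout probability in `[0, 1)` (default 0.5).
#' @param batch_size mini-batch size (default 32).
#' @param max_epochs training-epoch cap (default 50).
#' @param early_stop_patience epochs without validation-loss improvement
#'   before stopping (default 3).
#' @param learning_rate Adam step size (default 1e-3).
#' @param seed integer seed controlling initialization, shuffling and dropout.
#' @return An object of class `model_config`.
#' @export
model_config <- function(n_channels = 6, window_len = 200, n_filters = 64,
                         kernel_len = 9, pool_len = 2, dense_units = 64,
                         dropout_rate = 0.5, batch_size = 32,
                         max_epochs = 50, early_stop_patience = 3,
                         learning_rate = 1e-3, seed = 1L) {
  if (!n_channels %in% c(3, 6)) iw_stop("n_channels must be 3 or 6", "config")
  if (dropout_rate < 0 || dropout_rate >= 1)
    iw_stop("dropout_rate must be in [0, 1)", "config")
  if (batch_size < 1) iw_stop("batch_size must be >= 1", "config")
  if (kernel_len >= window_len)
    iw_stop("kernel_len must be smaller than window_len", "config")
  if (kernel_len %% 2 != 1) iw_stop("kernel_len must be odd", "config")
  if (learning_rate <= 0) iw_stop("learning_rate must be positive", "config")
  l1 <- window_len - kernel_len + 1
  l2 <- l1 - kernel_len + 1
  if (l2 < pool_len)
    iw_stop("window_len too short for kernel/pool configuration", "config")
  structure(list(n_channels = as.integer(n_channels),
                 window_len = as.integer(window_len),
                 n_filters = as.integer(n_filters),
                 kernel_len = as.integer(kernel_len),
                 pool_len = as.integer(pool_len),
                 dense_units = as.integer(dense_units),
                 dropout_rate = dropout_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 learning_rate = learning_rate,
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Parameter count implied by a configuration
#'
#' @param cfg a [model_config()].
#' @return Total number of trainable weights and biases.
#' @export
count_cnn_params <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  l1 <- cfg$window_len - cfg$kernel_len + 1
  l2 <- l1 - cfg$kernel_len + 1
  flat <- (l2 %/% cfg$pool_len) * cfg$n_filters
  (cfg$kernel_len * cfg$n_channels + 1) * cfg$n_filters +
    (cfg$kernel_len * cfg$n_filters + 1) * cfg$n_filters +
    (flat + 1) * cfg$dense_units +
    (cfg$dense_units + 1) * 2
}

#' Build an untrained CNN with seeded initialization
#'
#' Weights use He-scaled normal initialization; two builds with the same
#' config (including seed) are identical.
#'
#' @param cfg a [model_config()].
#' @return An object of class `cnn_model`.
#' @export
build_cnn <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  params <- cnn_init_cpp(unclass(cfg))
  structure(list(config = cfg, params = params,
                 n_params = sum(vapply(params, length, numeric(1))),
                 class_order = c("non-walking", "walking")),
            class = "cnn_model")
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf("<cnn_model> untrained | %d channels x %d samples | %d filters | %s parameters\n",
              x$config$n_channels, x$config$window_len, x$config$n_filters,
              format(x$n_params, big.mark = ",")))
  invisible(x)
}

check_model_input <- function(ws, cfg, role) {
  if (!ws$normalized)
    iw_stop(sprintf("%s windows must be normalized before use", role), "state")
  d <- dim(ws$windows)
  if (d[3] != cfg$n_channels)
    iw_stop(sprintf("%s windows have %d channels but model expects %d",
                    role, d[3], cfg$n_channels), "config")
  if (d[2] != cfg$window_len)
    iw_stop(sprintf("%s window length %d does not match model window_len %d",
                    role, d[2], cfg$window_len), "config")
}

#' Train the CNN with early stopping
#'
#' Minimizes cross-entropy with Adam in mini-batches of `cfg$batch_size`.
#' Training stops at `max_epochs` or after `early_stop_patience` consecutive
#' epochs without validation-loss improvement; the best-validation-loss
#' parameters are restored. Fully deterministic given the config seed.
#'
#' @param model a [build_cnn()] model.
#' @param train_ws normalized, class-balanced training [window_set()].
#' @param val_ws normalized validation [window_set()].
#' @return An object of class `trained_cnn` with per-epoch history.
#' @export
train_cnn <- function(model, train_ws, val_ws) {
  stopifnot(inherits(model, "cnn_model"))
  cfg <- model$config
  check_model_input(train_ws, cfg, "training")
  check_model_input(val_ws, cfg, "validation")
  if (n_windows(train_ws) == 0) iw_stop("empty training set", "data")
  if (n_windows(val_ws) == 0) iw_stop("empty validation set", "data")
  if (sum(train_ws$labels == 1L) != sum(train_ws$labels == 0L))
    warning("training windows are not class-balanced")
  fit <- cnn_train_cpp(train_ws$windows, train_ws$labels,
                       val_ws$windows, val_ws$labels,
                       unclass(cfg), model$params)
  structure(list(config = cfg,
                 params = fit$params,
                 history = data.frame(epoch = seq_along(fit$train_loss),
                                      train_loss = fit$train_loss,
                                      val_loss = fit$val_loss),
                 best_epoch = fit$best_epoch,
                 best_val_loss = fit$best_val_loss,
                 class_order = model$class_order),
            class = "trained_cnn")
}

#' @export
print.trained_cnn <- function(x, ...) {
  cat(sprintf("<trained_cnn> %d channels | %d epochs run, best epoch %d (val loss %.4f)\n",
              x$config$n_channels, nrow(x$history), x$best_epoch,
              x$best_val_loss))
  invisible(x)
}

#' Predict walking probabilities for windows
#'
#' @param object a `trained_cnn`.
#' @param ws a normalized [window_set()] with matching channels.
#' @param ... unused.
#' @return A list with `prob` (n x 2 matrix, columns `non-walking`,
#'   `walking`, rows summing to 1) and `label` (0/1 hard labels by argmax).
#' @export
predict.trained_cnn <- function(object, ws, ...) {
  check_model_input(ws, object$config, "prediction")
  if (n_windows(ws) == 0)
    return(list(prob = matrix(numeric(0), 0, 2,
                              dimnames = list(NULL, object$class_order)),
                label = integer(0)))
  prob <- cnn_predict_cpp(ws$windows, unclass(object$config), object$params)
  colnames(prob) <- object$class_order
  list(prob = prob, label = as.integer(prob[, 2] > prob[, 1]))
}

#' Save a trained model as a directory artifact
#'
#' Writes `config.txt` (key-value hyperparameters), `history.tsv` (per-epoch
#' losses), and `params.rds` (the learned weights).
#'
#' @param tm a `trained_cnn`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
save_model <- function(tm, dir) {
  stopifnot(inherits(tm, "trained_cnn"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- unclass(tm$config)
  writeLines(c(sprintf("%s: %s", names(cfg), unlist(cfg)),
               sprintf("best_epoch: %d", tm$best_epoch),
               sprintf("class_order: %s", paste(tm$class_order,
                                                collapse = ","))),
             file.path(dir, "config.txt"))
  write.table(tm$history, file.path(dir, "history.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  saveRDS(tm$params, file.path(dir, "params.rds"))
  invisible(dir)
}

#' Load a model saved by [save_model()]
#'
#' @param dir model directory.
#' @return A `trained_cnn`.
#' @export
load_model <- function(dir) {
  cfg_lines <- readLines(file.path(dir, "config.txt"))
  kv <- strsplit(cfg_lines, ": ", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, character(1), 2),
                          vapply(kv, `[`, character(1), 1))
  num <- function(k) as.numeric(vals[[k]])
  cfg <- model_config(n_channels = num("n_channels"),
                      window_len = num("window_len"),
                      n_filters = num("n_filters"),
                      kernel_len = num("kernel_len"),
                      pool_len = num("pool_len"),
                      dense_units = num("dense_units"),
                      dropout_rate = num("dropout_rate"),
                      batch_size = num("batch_size"),
                      max_epochs = num("max_epochs"),
                      early_stop_patience = num("early_stop_patience"),
                      learning_rate = num("learning_rate"),
                      seed = num("seed"))
  history <- read.table(file.path(dir, "history.tsv"), header = TRUE,
                        sep = "\t")
  structure(list(config = cfg,
                 params = readRDS(file.path(dir, "params.rds")),
                 history = history,
                 best_epoch = as.integer(num("best_epoch")),
                 best_val_loss = min(history$val_loss),
                 class_order = strsplit(vals[["class_order"]], ",")[[1]]),
            class = "trained_cnn")
}
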