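# Fixtures are built in code: tiny recordings, separable window sets, and a
# scaled-down model configuration that keeps unit tests fast.

tiny_synth_cfg <- function(n = 3, duration = 120, seed = 11, ...) {
  synthetic_config(n_participants = n, total_duration_s = duration,
                   seed = seed, ...)
}

tiny_model_cfg <- function(n_channels = 3, window_len = 60, seed = 1,
                           max_epochs = 15, ...) {
  model_config(n_channels = n_channels, window_len = window_len,
               n_filters = 8, kernel_len = 5, pool_len = 2, dense_units = 16,
               batch_size = 16, max_epochs = max_epochs, seed = seed, ...)
}

# hand-built recording with known samples and labels
make_rec <- function(T = 400, C = 6, id = "P01", labels = NULL, fs = 100) {
  set.seed(99)
  samples <- matrix(rnorm(T * C), T, C)
  labels <- labels %||% rep(c("walking", "sitting"), length.out = T)
  imu_recording(id, samples, labels, fs)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# high-amplitude periodic windows (walking) vs near-flat noise (non-walking);
# any competent classifier separates them
make_separable_ws <- function(n_per_class, W = 60, C = 3, seed = 42) {
  set.seed(seed)
  n <- 2L * n_per_class
  w <- array(rnorm(n * W * C, sd = 0.2), c(n, W, C))
  t <- (seq_len(W) - 1) / 100
  for (i in seq_len(n_per_class)) {
    phase <- runif(1, 0, 2 * pi)
    base <- 3 * sin(2 * pi * 8 * t + phase)
    w[i, , 1] <- w[i, , 1] + 0.5 * base
    w[i, , C] <- w[i, , C] + base
  }
  labels <- rep(c(1L, 0L), each = n_per_class)
  ws <- window_set(w, labels, rep("SYN", n), W, 0.5)
  normalize_windows(ws)
}

# random valid window set for round-trip / rotation property tests
random_ws <- function(n = 9, W = 200, C = 6, seed = 1) {
  set.seed(seed)
  window_set(array(rnorm(n * W * C), c(n, W, C)),
             labels = sample(0:1, n, replace = TRUE),
             participant_ids = sample(c("A", "B"), n, replace = TRUE),
             window_len = W, overlap = 0.5,
             augmented_from = sample(c(NA, "x+1"), n, replace = TRUE))
}

write_toy_recording_file <- function(path, gyro = TRUE, two_ids = FALSE,
                                     header_rate = TRUE) {
  cols <- c("participant_id", "label", "ax", "ay", "az",
            if (gyro) c("gx", "gy", "gz"))
  ids <- if (two_ids) c("P1", "P2", "P1", "P2", "P1") else rep("P1", 3)
  n <- length(ids)
  df <- data.frame(participant_id = ids,
                   label = rep(c("walking", "sitting"), length.out = n))
  for (s in cols[-(1:2)]) df[[s]] <- round(seq_len(n) + match(s, cols), 3)
  lines <- c(if (header_rate) "# sampling_rate_hz: 100",
             paste(cols, collapse = ","),
             do.call(paste, c(unname(df[cols]), sep = ",")))
  writeLines(lines, path)
  df
}
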