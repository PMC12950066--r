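# Window-level preprocessing: label binarization, sliding-window
# segmentation, per-window mean normalization, quarter-turn rotation
# augmentation, and majority-class down-sampling.

#' Construct a window set
#'
#' Fixed-length signal windows with binary labels (1 = walking,
#' 0 = non-walking) and participant provenance, the unit of classification.
#'
#' @param windows numeric array, n x window_len x channels (3 or 6).
#' @param labels integer vector of 0/1 window labels, length n.
#' @param participant_ids character vector, length n.
#' @param window_len window length in samples.
#' @param overlap overlap fraction in `[0, 1)`.
#' @param normalized logical: have per-axis window means been subtracted?
#' @param augmented_from per-window rotation tag (`NA` for original windows).
#' @return An object of class `window_set`.
#' @export
window_set <- function(windows, labels, participant_ids,
                       window_len = dim(windows)[2], overlap = 0.5,
                       normalized = FALSE, augmented_from = NULL) {
  if (length(dim(windows)) != 3)
    iw_stop("windows must be a 3-d array (n x window_len x channels)",
            "argument")
  n <- dim(windows)[1]
  if (length(labels) != n || length(participant_ids) != n)
    iw_stop("labels and participant_ids must match the number of windows",
            "argument")
  if (!dim(windows)[3] %in% c(3L, 6L))
    iw_stop("windows must have 3 or 6 channels", "argument")
  if (window_len < 2) iw_stop("window_len must be >= 2", "argument")
  if (overlap < 0 || overlap >= 1)
    iw_stop("overlap must be in [0, 1)", "argument")
  structure(list(windows = windows,
                 labels = as.integer(labels),
                 participant_ids = as.character(participant_ids),
                 window_len = as.integer(window_len),
                 overlap = overlap,
                 normalized = isTRUE(normalized),
                 augmented_from = augmented_from %||% rep(NA_character_, n)),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  n <- dim(x$windows)[1]
  cat(sprintf("<window_set> %d windows x %d samples x %d channels | walking %d / non-walking %d%s%s\n",
              n, dim(x$windows)[2], dim(x$windows)[3],
              sum(x$labels == 1L), sum(x$labels == 0L),
              if (x$normalized) " | normalized" else "",
              if (any(!is.na(x$augmented_from))) " | augmented" else ""))
  invisible(x)
}

#' Number of windows in a window set
#' @param ws a [window_set()].
#' @return Integer count.
#' @export
n_windows <- function(ws) dim(ws$windows)[1]

#' Binarize per-sample activity labels
#'
#' Maps every label in the walking set to 1 and any other label — including
#' dynamic non-gait activities such as shuffling, stair ascent or transitions
#' — to 0.
#'
#' @param rec an [imu_recording()].
#' @param label_set an [activity_label_set()].
#' @return Integer vector of 0/1, one per sample.
#' @export
binarize_labels <- function(rec, label_set = activity_label_set()) {
  stopifnot(inherits(rec, "imu_recording"),
            inherits(label_set, "activity_label_set"))
  as.integer(rec$labels %in% label_set$walking_labels)
}

#' Segment a recording into overlapping fixed-length windows
#'
#' Windows start every `round(window_len * (1 - overlap))` samples; trailing
#' samples that do not fill a whole window are discarded. Each window gets a
#' single binary label by majority vote over its per-sample labels, with ties
#' resolved to non-walking.
#'
#' @param rec an [imu_recording()].
#' @param binary_labels optional 0/1 per-sample labels; computed from
#'   `label_set` when `NULL`.
#' @param window_len window length in samples (default 200, i.e. 2 s at
#'   100 Hz).
#' @param overlap overlap fraction (default 0.5).
#' @param label_set an [activity_label_set()] used when `binary_labels` is
#'   `NULL`.
#' @return A [window_set()]; empty (with a warning) when the recording is
#'   shorter than one window.
#' @export
segment <- function(rec, binary_labels = NULL, window_len = 200,
                    overlap = 0.5, label_set = activity_label_set()) {
  stopifnot(inherits(rec, "imu_recording"))
  if (window_len < 2) iw_stop("window_len must be >= 2", "argument")
  if (overlap < 0 || overlap >= 1)
    iw_stop("overlap must be in [0, 1)", "argument")
  step <- round(window_len * (1 - overlap))
  if (step < 1) iw_stop("window step must be >= 1", "argument")
  bl <- binary_labels %||% binarize_labels(rec, label_set)
  if (length(bl) != nrow(rec$samples))
    iw_stop("binary_labels length must equal number of samples", "argument")
  T_ <- nrow(rec$samples)
  C <- ncol(rec$samples)
  if (T_ < window_len) {
    warning(sprintf("recording %s shorter than one window (%d < %d); no windows",
                    rec$participant_id, T_, window_len))
    return(window_set(array(0, dim = c(0, window_len, C)), integer(0),
                      character(0), window_len, overlap))
  }
  n <- (T_ - window_len) %/% step + 1L
  starts <- (seq_len(n) - 1L) * step + 1L
  idx <- outer(0:(window_len - 1L), starts, "+")  # window_len x n
  windows <- array(0, dim = c(n, window_len, C))
  for (c_ in seq_len(C))
    windows[, , c_] <- t(matrix(rec$samples[idx, c_], window_len, n))
  # majority vote via cumulative sums; strict > so a tie maps to non-walking
  cs <- c(0, cumsum(bl))
  walk_counts <- cs[starts + window_len] - cs[starts]
  labels <- as.integer(walk_counts > window_len / 2)
  window_set(windows, labels, rep(rec$participant_id, n), window_len, overlap)
}

#' Subtract each window's per-axis mean
#'
#' Normalization is per window and per axis, applied after segmentation;
#' gravity and posture offsets are removed window by window. Labels and
#' provenance are unchanged and the `normalized` flag is set.
#'
#' @param ws a [window_set()] not yet normalized.
#' @return The normalized [window_set()].
#' @export
normalize_windows <- function(ws) {
  stopifnot(inherits(ws, "window_set"))
  if (ws$normalized) iw_stop("window set is already normalized", "state")
  n <- n_windows(ws)
  if (n > 0) {
    C <- dim(ws$windows)[3]
    W <- dim(ws$windows)[2]
    m <- colMeans(aperm(ws$windows, c(2, 1, 3)))        # n x C
    ws$windows <- ws$windows - aperm(array(m, dim = c(n, C, W)), c(1, 3, 2))
  }
  ws$normalized <- TRUE
  ws
}

rotation_matrix_90 <- function(axis, quarter_turns) {
  if (!axis %in% c("x", "y", "z"))
    iw_stop("axis must be one of 'x', 'y', 'z'", "argument")
  if (length(quarter_turns) != 1 || quarter_turns != round(quarter_turns))
    iw_stop("quarter_turns must be an integer", "argument")
  theta <- (quarter_turns %% 4) * pi / 2
  co <- round(cos(theta)); si <- round(sin(theta))
  switch(axis,
         x = matrix(c(1, 0, 0, 0, co, si, 0, -si, co), 3, 3),
         y = matrix(c(co, 0, -si, 0, 1, 0, si, 0, co), 3, 3),
         z = matrix(c(co, si, 0, -si, co, 0, 0, 0, 1), 3, 3))
}

rotate_triads <- function(mat, R) {
  C <- ncol(mat)
  out <- mat
  out[, 1:3] <- mat[, 1:3] %*% t(R)
  if (C == 6L) out[, 4:6] <- mat[, 4:6] %*% t(R)
  out
}

#' Rotate sensor triads by quarter turns about a sensor axis
#'
#' Applies the right-handed 3x3 rotation for `quarter_turns` x 90 degrees
#' about the named axis to the accelerometer triad and, when present,
#' identically to the gyroscope triad — a rigid re-mounting of the sensor.
#' Per-sample triad norms are preserved; labels are untouched.
#'
#' @param x a [window_set()], [imu_recording()], or T x 3/6 numeric matrix.
#' @param axis one of `"x"`, `"y"`, `"z"`.
#' @param quarter_turns integer number of 90-degree turns (may be negative).
#' @param ... unused.
#' @return An object of the same type as `x`.
#' @export
rotate90 <- function(x, axis, quarter_turns = 1L, ...) UseMethod("rotate90")

#' @rdname rotate90
#' @export
rotate90.matrix <- function(x, axis, quarter_turns = 1L, ...) {
  if (!ncol(x) %in% c(3L, 6L)) iw_stop("matrix must have 3 or 6 columns",
                                       "argument")
  rotate_triads(x, rotation_matrix_90(axis, quarter_turns))
}

#' @rdname rotate90
#' @export
rotate90.imu_recording <- function(x, axis, quarter_turns = 1L, ...) {
  x$samples <- rotate_triads(x$samples, rotation_matrix_90(axis, quarter_turns))
  x$source <- sprintf("%s [rotated %s%+d]", x$source, axis, quarter_turns)
  x
}

#' @rdname rotate90
#' @export
rotate90.window_set <- function(x, axis, quarter_turns = 1L, ...) {
  R <- rotation_matrix_90(axis, quarter_turns)
  d <- dim(x$windows)
  acc <- x$windows[, , 1:3, drop = FALSE]
  dim(acc) <- c(d[1] * d[2], 3)
  acc <- acc %*% t(R)
  dim(acc) <- c(d[1], d[2], 3)
  x$windows[, , 1:3] <- acc
  if (d[3] == 6L) {
    gyr <- x$windows[, , 4:6, drop = FALSE]
    dim(gyr) <- c(d[1] * d[2], 3)
    gyr <- gyr %*% t(R)
    dim(gyr) <- c(d[1], d[2], 3)
    x$windows[, , 4:6] <- gyr
  }
  x
}

#' Default augmentation rotations
#'
#' One quarter turn about each sensor axis, emulating major sensor placement
#' shifts in three orthogonal directions.
#'
#' @return A list of `list(axis, quarter_turns)` entries.
#' @export
default_rotations <- function() {
  list(list(axis = "x", quarter_turns = 1L),
       list(axis = "y", quarter_turns = 1L),
       list(axis = "z", quarter_turns = 1L))
}

#' Expand a window set with rotated copies
#'
#' Output contains the original windows plus one rotated copy per listed
#' rotation; copies inherit labels and participant IDs and carry an
#' `augmented_from` tag such as `"x+1"`.
#'
#' @param ws a [window_set()].
#' @param rotations list of `list(axis, quarter_turns)`; default
#'   [default_rotations()]. An empty list returns `ws` unchanged.
#' @return A [window_set()] with `n * (1 + length(rotations))` windows.
#' @export
augment <- function(ws, rotations = default_rotations()) {
  stopifnot(inherits(ws, "window_set"))
  if (length(rotations) == 0) return(ws)
  pieces <- c(list(ws), lapply(rotations, function(r) {
    out <- rotate90(ws, r$axis, r$quarter_turns)
    out$augmented_from <- rep(sprintf("%s%+d", r$axis, r$quarter_turns),
                              n_windows(ws))
    out
  }))
  combine_windows(pieces)
}

#' Concatenate window sets
#'
#' All sets must share window length, overlap, channel count, and
#' normalization state.
#'
#' @param ws_list list of [window_set()] objects.
#' @return A single combined [window_set()].
#' @export
combine_windows <- function(ws_list) {
  stopifnot(length(ws_list) >= 1, all(vapply(ws_list, inherits, TRUE,
                                             "window_set")))
  ref <- ws_list[[1]]
  for (w in ws_list[-1]) {
    if (w$window_len != ref$window_len || dim(w$windows)[3] != dim(ref$windows)[3] ||
        w$normalized != ref$normalized)
      iw_stop("window sets are not compatible for combination", "argument")
  }
  ns <- vapply(ws_list, n_windows, integer(1))
  total <- sum(ns)
  d <- dim(ref$windows)
  windows <- array(0, dim = c(total, d[2], d[3]))
  pos <- 0L
  for (w in ws_list) {
    if (n_windows(w) > 0)
      windows[pos + seq_len(n_windows(w)), , ] <- w$windows
    pos <- pos + n_windows(w)
  }
  window_set(windows,
             unlist(lapply(ws_list, `[[`, "labels")) %||% integer(0),
             unlist(lapply(ws_list, `[[`, "participant_ids")) %||% character(0),
             ref$window_len, ref$overlap, ref$normalized,
             unlist(lapply(ws_list, `[[`, "augmented_from")) %||% character(0))
}

#' Subset a window set by index
#'
#' @param ws a [window_set()].
#' @param idx integer index vector.
#' @return The subsetted [window_set()].
#' @export
subset_windows <- function(ws, idx) {
  window_set(ws$windows[idx, , , drop = FALSE], ws$labels[idx],
             ws$participant_ids[idx], ws$window_len, ws$overlap,
             ws$normalized, ws$augmented_from[idx])
}

#' Keep only the acceleration channels
#'
#' Slices 6-channel windows down to `(ax, ay, az)` for the 3-channel model;
#' a 3-channel set is returned unchanged.
#'
#' @param ws a [window_set()].
#' @return A 3-channel [window_set()].
#' @export
acc_only <- function(ws) {
  if (dim(ws$windows)[3] == 3L) return(ws)
  window_set(ws$windows[, , 1:3, drop = FALSE], ws$labels,
             ws$participant_ids, ws$window_len, ws$overlap, ws$normalized,
             ws$augmented_from)
}

#' Balance classes by down-sampling the majority
#'
#' The minority class is kept intact; the majority class is randomly
#' down-sampled without replacement to the minority count. Original window
#' order is preserved. Applied to training and validation pools only — test
#' pools are never balanced.
#'
#' @param ws a [window_set()] containing both classes.
#' @param seed integer seed for the down-sampling draw.
#' @return A [window_set()] with equal class counts.
#' @export
balance_windows <- function(ws, seed = 1L) {
  stopifnot(inherits(ws, "window_set"))
  n1 <- sum(ws$labels == 1L)
  n0 <- sum(ws$labels == 0L)
  if (n1 == 0 || n0 == 0)
    iw_stop("both classes must be present to balance", "balance")
  if (n1 == n0) return(ws)
  minority <- if (n1 < n0) 1L else 0L
  maj_idx <- which(ws$labels != minority)
  keep_maj <- with_seed(seed, sample(maj_idx, min(n1, n0)))
  subset_windows(ws, sort(c(which(ws$labels == minority), keep_maj)))
}
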