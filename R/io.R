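# Recording and window-set containers, plus their on-disk dialects.

SIGNAL_COLS_6 <- c("ax", "ay", "az", "gx", "gy", "gz")
SIGNAL_COLS_3 <- c("ax", "ay", "az")

#' Labeled IMU recording for one participant
#'
#' A continuous multi-channel inertial signal from a single lower-back sensor
#' with a per-sample activity label. Channels are ordered
#' `(ax, ay, az[, gx, gy, gz])`: tri-axial acceleration in m/s^2 and,
#' optionally, tri-axial angular velocity in deg/s.
#'
#' @param participant_id single string identifying the wearer.
#' @param samples numeric matrix, T x 3 or T x 6, no non-finite values.
#' @param labels character vector of per-sample activity names, length T.
#' @param sampling_rate_hz positive sampling frequency (nominally 100).
#' @param source free-text provenance note.
#' @return An object of class `imu_recording`.
#' @export
imu_recording <- function(participant_id, samples, labels,
                          sampling_rate_hz = 100, source = "") {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (!ncol(samples) %in% c(3L, 6L))
    iw_stop("samples must have 3 or 6 channels", "format")
  if (length(labels) != nrow(samples))
    iw_stop("labels length must equal number of sample rows", "format")
  if (!is.numeric(sampling_rate_hz) || length(sampling_rate_hz) != 1 ||
      sampling_rate_hz <= 0)
    iw_stop("sampling_rate_hz must be a positive number", "format")
  bad <- which(!is.finite(samples))
  if (length(bad)) {
    row <- ((bad[1] - 1) %% nrow(samples)) + 1
    iw_stop(sprintf("non-finite sample value at row %d", row), "data")
  }
  colnames(samples) <- if (ncol(samples) == 6L) SIGNAL_COLS_6 else SIGNAL_COLS_3
  structure(list(participant_id = as.character(participant_id),
                 sampling_rate_hz = as.numeric(sampling_rate_hz),
                 samples = samples,
                 labels = as.character(labels),
                 source = source),
            class = "imu_recording")
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording> participant %s: %d samples x %d channels @ %g Hz (%.1f s)\n",
              x$participant_id, nrow(x$samples), ncol(x$samples),
              x$sampling_rate_hz, nrow(x$samples) / x$sampling_rate_hz))
  tab <- sort(table(x$labels), decreasing = TRUE)
  cat("  labels:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Define which activity labels count as walking
#'
#' Every label in `walking_labels` is mapped to the positive (walking) class;
#' any other label, known or not, is non-walking.
#'
#' @param walking_labels non-empty character vector (default `"walking"`).
#' @return An object of class `activity_label_set`.
#' @export
activity_label_set <- function(walking_labels = "walking") {
  if (!is.character(walking_labels) || length(walking_labels) == 0)
    iw_stop("walking_labels must be a non-empty character vector", "argument")
  structure(list(walking_labels = walking_labels),
            class = "activity_label_set")
}

#' Read labeled IMU recordings from a delimited text file
#'
#' The file is UTF-8 delimited text with a header row containing
#' `participant_id`, `label`, and either 3 (`ax,ay,az`) or 6
#' (`ax,...,gz`) signal columns. The sampling rate may be given as a header
#' comment line `# sampling_rate_hz: <value>` or via the argument; the
#' argument wins when both are present.
#'
#' @param path file path.
#' @param sampling_rate_hz sampling rate override; `NULL` to read it from the
#'   header comment (error if absent from both).
#' @param sep field separator (default `","`).
#' @return A list of [imu_recording()] objects, one per distinct participant,
#'   rows kept in original temporal order.
#' @export
read_recordings <- function(path, sampling_rate_hz = NULL, sep = ",") {
  if (!file.exists(path)) iw_stop(sprintf("file not found: %s", path), "io")
  if (is.null(sampling_rate_hz)) {
    head_lines <- readLines(path, n = 5L)
    m <- regmatches(head_lines,
                    regexpr("^#\\s*sampling_rate_hz\\s*:\\s*[0-9.]+", head_lines))
    if (length(m))
      sampling_rate_hz <- as.numeric(sub(".*:\\s*", "", m[1]))
    else
      iw_stop("sampling rate not in file header; supply sampling_rate_hz",
              "format")
  }
  df <- read.table(path, header = TRUE, sep = sep, comment.char = "#",
                   stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c("participant_id", "label"))
    if (!col %in% names(df))
      iw_stop(sprintf("missing required column: %s", col), "format")
  has6 <- all(SIGNAL_COLS_6 %in% names(df))
  has3 <- all(SIGNAL_COLS_3 %in% names(df))
  if (!has3)
    iw_stop(sprintf("missing signal column: %s",
                    setdiff(SIGNAL_COLS_3, names(df))[1]), "format")
  partial_gyro <- !has6 && any(c("gx", "gy", "gz") %in% names(df))
  if (partial_gyro)
    iw_stop(sprintf("missing signal column: %s",
                    setdiff(c("gx", "gy", "gz"), names(df))[1]), "format")
  sig_cols <- if (has6) SIGNAL_COLS_6 else SIGNAL_COLS_3
  ids <- unique(df$participant_id)
  lapply(ids, function(id) {
    rows <- df$participant_id == id
    imu_recording(participant_id = id,
                  samples = as.matrix(df[rows, sig_cols, drop = FALSE]),
                  labels = df$label[rows],
                  sampling_rate_hz = sampling_rate_hz,
                  source = path)
  })
}

#' Write one recording to delimited text
#'
#' Inverse of [read_recordings()]: writes a `# sampling_rate_hz:` header
#' comment followed by a header row and one row per sample.
#'
#' @param rec an [imu_recording()].
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, sep = ",") {
  stopifnot(inherits(rec, "imu_recording"))
  df <- data.frame(participant_id = rec$participant_id,
                   label = rec$labels,
                   rec$samples,
                   check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sampling_rate_hz: %g", rec$sampling_rate_hz), con)
  write.table(df, con, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Linearly resample a recording to a target rate
#'
#' Each signal channel is linearly interpolated onto a uniform time grid at
#' `target_hz`; each resampled point takes the label of the nearest original
#' sample. Used to bring recordings at other rates (e.g. 104 Hz) to the
#' model's training rate before segmentation.
#'
#' @param rec an [imu_recording()].
#' @param target_hz positive target sampling rate.
#' @return A resampled [imu_recording()].
#' @export
resample_recording <- function(rec, target_hz = 100) {
  stopifnot(inherits(rec, "imu_recording"))
  if (rec$sampling_rate_hz == target_hz) return(rec)
  t_old <- (seq_len(nrow(rec$samples)) - 1) / rec$sampling_rate_hz
  t_new <- seq(0, t_old[length(t_old)], by = 1 / target_hz)
  samples <- vapply(seq_len(ncol(rec$samples)), function(c)
    approx(t_old, rec$samples[, c], xout = t_new)$y,
    numeric(length(t_new)))
  idx <- pmin(length(t_old), pmax(1L, round(t_new * rec$sampling_rate_hz) + 1L))
  imu_recording(rec$participant_id, samples, rec$labels[idx], target_hz,
                source = paste0(rec$source, " [resampled to ", target_hz, " Hz]"))
}

#' Serialize a window set to a single-file container
#'
#' The container is a tagged RDS file holding the window array, labels,
#' participant provenance, and the metadata block (window length, overlap,
#' channel count, normalization flag, augmentation tags). Round-trip through
#' [read_windows()] is lossless for every field.
#'
#' @param ws a [window_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_windows <- function(ws, path) {
  stopifnot(inherits(ws, "window_set"))
  obj <- unclass(ws)
  obj$.format <- "imuwalk_windows"
  obj$.version <- 1L
  ok <- tryCatch({ saveRDS(obj, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) iw_stop(sprintf("cannot write window container: %s", path), "io")
  invisible(path)
}

#' Read a window set container written by [write_windows()]
#'
#' @param path file path.
#' @return A [window_set()].
#' @export
read_windows <- function(path) {
  if (!file.exists(path)) iw_stop(sprintf("file not found: %s", path), "io")
  obj <- tryCatch(readRDS(path), error = function(e)
    iw_stop(sprintf("corrupted window container: %s", path), "format"))
  if (!identical(obj$.format, "imuwalk_windows"))
    iw_stop("not an imuwalk window container", "format")
  obj$.format <- NULL
  obj$.version <- NULL
  class(obj) <- "window_set"
  obj
}
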