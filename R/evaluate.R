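# Confusion-matrix metrics, class-ratio bookkeeping, repeated hold-out
# orchestration, sensitivity-based model selection and median(IQR) summaries.

#' Confusion counts with walking as the positive class
#'
#' @param pred integer 0/1 predicted labels.
#' @param truth integer 0/1 true labels of the same length.
#' @return Named integer vector `c(tp, fp, tn, fn)`.
#' @export
confusion <- function(pred, truth) {
  if (length(pred) != length(truth))
    iw_stop("pred and truth must have equal length", "argument")
  if (length(pred) < 1) iw_stop("need at least one window", "argument")
  c(tp = sum(pred == 1L & truth == 1L),
    fp = sum(pred == 1L & truth == 0L),
    tn = sum(pred == 0L & truth == 0L),
    fn = sum(pred == 0L & truth == 1L))
}

#' Five evaluation metrics from confusion counts
#'
#' Computes accuracy, precision, sensitivity (recall of walking), F1-score
#' and specificity. A metric whose denominator is zero is reported as 0 and
#' named in `flags` rather than failing, so degenerate all-one-class
#' predictions do not interrupt a repeat loop.
#'
#' @param tp,fp,tn,fn non-negative confusion counts (walking = positive).
#'   `tp` may also be the named vector returned by [confusion()].
#' @param tags optional named list of context tags (role, channels,
#'   augmented, repeat index) carried along in reports.
#' @return An object of class `metrics_report`.
#' @export
metrics <- function(tp, fp = NULL, tn = NULL, fn = NULL, tags = list()) {
  if (is.null(fp) && length(tp) == 4) {
    fp <- tp[["fp"]]; tn <- tp[["tn"]]; fn <- tp[["fn"]]; tp <- tp[["tp"]]
  }
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts)))
    iw_stop("confusion counts must be non-negative integers", "argument")
  n <- sum(counts)
  if (n < 1) iw_stop("confusion counts sum to zero", "argument")
  flags <- character(0)
  safe_div <- function(num, den, name) {
    if (den == 0) { flags <<- c(flags, name); return(0) }
    num / den
  }
  precision <- safe_div(tp, tp + fp, "precision")
  sensitivity <- safe_div(tp, tp + fn, "sensitivity")
  specificity <- safe_div(tn, tn + fp, "specificity")
  f1 <- safe_div(2 * precision * sensitivity, precision + sensitivity, "f1")
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 accuracy = (tp + tn) / n,
                 precision = precision,
                 sensitivity = sensitivity,
                 f1 = f1,
                 specificity = specificity,
                 n_windows = n,
                 flags = flags,
                 tags = tags),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n=%d | acc %.3f | prec %.3f | sens %.3f | F1 %.3f | spec %.3f%s\n",
              x$n_windows, x$accuracy, x$precision, x$sensitivity, x$f1,
              x$specificity,
              if (length(x$flags)) paste0(" | zero-denominator: ",
                                          paste(x$flags, collapse = ",")) else ""))
  invisible(x)
}

#' Non-walking to walking window ratio
#'
#' Reported as `1:r` with `r = non-walking / walking` rounded to 2 decimals,
#' the conventional statement of window-level class imbalance.
#'
#' @param x a [window_set()], or the walking window count when `non_walking`
#'   is supplied.
#' @param non_walking non-walking window count (when `x` is a count).
#' @return A list with `r` (rounded ratio) and `label` (e.g. `"1:8.61"`).
#' @export
class_ratio <- function(x, non_walking = NULL) {
  if (inherits(x, "window_set")) {
    walking <- sum(x$labels == 1L)
    non_walking <- sum(x$labels == 0L)
  } else {
    walking <- x
  }
  if (walking == 0) iw_stop("no walking windows; ratio undefined", "ratio")
  r <- round(non_walking / walking, 2)
  list(r = r, label = sprintf("1:%.2f", r))
}

metric_names <- c("accuracy", "precision", "sensitivity", "f1", "specificity")

#' Median and IQR of metrics across repeats
#'
#' Quartiles use linear interpolation of order statistics
#' (`quantile(..., type = 5)`); IQR is the 75th minus the 25th percentile.
#'
#' @param reports list of [metrics()] reports.
#' @return A data frame with one row per metric: `median` and `iqr`.
#' @export
summarize_metrics <- function(reports) {
  stopifnot(length(reports) >= 1)
  vals <- vapply(reports, function(r)
    unlist(r[metric_names]), numeric(length(metric_names)))
  vals <- matrix(vals, nrow = length(metric_names),
                 dimnames = list(metric_names, NULL))
  data.frame(metric = metric_names,
             median = apply(vals, 1, median),
             iqr = apply(vals, 1, function(v)
               diff(unname(quantile(v, c(0.25, 0.75), type = 5)))),
             row.names = NULL)
}

#' Select the best model by validation sensitivity
#'
#' Ties on sensitivity are broken by higher F1, then by lower repeat index
#' (candidate order).
#'
#' @param candidates list of `list(model =, metrics =)` entries where
#'   `metrics` is a [metrics()] report on the validation pool.
#' @return The winning candidate (with its metrics).
#' @export
select_best <- function(candidates) {
  if (length(candidates) == 0) iw_stop("no candidates to select from",
                                       "argument")
  sens <- vapply(candidates, function(c) c$metrics$sensitivity, numeric(1))
  f1 <- vapply(candidates, function(c) c$metrics$f1, numeric(1))
  ord <- order(-sens, -f1, seq_along(candidates))
  candidates[[ord[1]]]
}

segment_pool <- function(recs, window_len, overlap, label_set) {
  combine_windows(lapply(recs, segment, window_len = window_len,
                         overlap = overlap, label_set = label_set))
}

# segment every recording once; repeats then only recombine per split
segment_by_participant <- function(recordings, window_len, overlap,
                                   label_set) {
  out <- lapply(recordings, segment, window_len = window_len,
                overlap = overlap, label_set = label_set)
  names(out) <- vapply(recordings, `[[`, character(1), "participant_id")
  out
}

#' Repeated participant-wise hold-out evaluation
#'
#' For each repeat and each grid cell (channel count x augmentation on/off):
#' split participants, segment, optionally augment train/validation windows
#' with quarter-turn rotations, normalize, balance train and validation
#' pools, train the CNN, and evaluate on the untouched test pool (never
#' augmented, never balanced). Splits are shared across cells within a
#' repeat so cells are compared on identical partitions.
#'
#' @param recordings list of [imu_recording()] objects (6 channels).
#' @param repeats number of hold-out repetitions R (default 10).
#' @param channels subset of `c(3, 6)` to evaluate.
#' @param augmented subset of `c(FALSE, TRUE)`: train without/with rotation
#'   augmentation.
#' @param rotations augmentation rotations (default [default_rotations()]).
#' @param fractions train/val/test participant fractions.
#' @param window_len,overlap segmentation parameters.
#' @param model_cfg base [model_config()]; its `n_channels` and `seed` are
#'   overridden per cell/repeat.
#' @param label_set an [activity_label_set()].
#' @param seed global seed; stage seeds are derived by fixed offsets.
#' @param keep_models keep each trained model in the result (memory-heavy).
#' @return An object of class `holdout_result`: per-cell test and validation
#'   reports, per-cell median(IQR) `summary`, and the sensitivity-selected
#'   `best` candidate per cell.
#' @export
repeated_holdout <- function(recordings, repeats = 10, channels = 3,
                             augmented = FALSE,
                             rotations = default_rotations(),
                             fractions = c(0.55, 0.25, 0.20),
                             window_len = 200, overlap = 0.5,
                             model_cfg = model_config(),
                             label_set = activity_label_set(),
                             seed = 1L, keep_models = FALSE) {
  if (repeats < 1) iw_stop("repeats must be >= 1", "argument")
  stopifnot(all(channels %in% c(3, 6)), is.logical(augmented))
  ids <- vapply(recordings, `[[`, character(1), "participant_id")
  grid <- expand.grid(channels = channels, augmented = augmented,
                      KEEP.OUT.ATTRS = FALSE)
  reports <- list()
  val_reports <- list()
  candidates <- rep(list(list()), nrow(grid))
  seg_by_id <- segment_by_participant(recordings, window_len, overlap,
                                      label_set)
  for (r in seq_len(repeats)) {
    split <- split_by_participant(ids, fractions, seed = seed + 1000L * r,
                                  repeat_index = r)
    train_raw <- combine_windows(seg_by_id[split$train_ids])
    val_raw <- combine_windows(seg_by_id[split$val_ids])
    test_raw <- combine_windows(seg_by_id[split$test_ids])
    for (g in seq_len(nrow(grid))) {
      ch <- grid$channels[g]
      da <- grid$augmented[g]
      slice <- function(ws) if (ch == 3) acc_only(ws) else ws
      tws <- slice(train_raw)
      vws <- slice(val_raw)
      if (da) {
        tws <- augment(tws, rotations)
        vws <- augment(vws, rotations)
      }
      tws <- balance_windows(normalize_windows(tws),
                             seed = seed + 1000L * r + 10L * g + 1L)
      vws <- balance_windows(normalize_windows(vws),
                             seed = seed + 1000L * r + 10L * g + 2L)
      test_ws <- normalize_windows(slice(test_raw))
      cfg <- model_cfg
      cfg$n_channels <- as.integer(ch)
      cfg$seed <- as.integer(seed + 1000L * r + 10L * g)
      tm <- train_cnn(build_cnn(cfg), tws, vws)
      tags <- list(channels = ch, augmented = da, repeat_index = r)
      test_pred <- predict(tm, test_ws)
      rep_test <- metrics(confusion(test_pred$label, test_ws$labels),
                          tags = c(tags, role = "test"))
      val_pred <- predict(tm, vws)
      rep_val <- metrics(confusion(val_pred$label, vws$labels),
                         tags = c(tags, role = "validation"))
      key <- sprintf("ch%d_da%s_r%d", ch, if (da) "on" else "off", r)
      reports[[key]] <- rep_test
      val_reports[[key]] <- rep_val
      candidates[[g]] <- c(candidates[[g]],
                           list(list(model = if (keep_models) tm else NULL,
                                     metrics = rep_val,
                                     test_metrics = rep_test,
                                     repeat_index = r)))
    }
  }
  summary <- do.call(rbind, lapply(seq_len(nrow(grid)), function(g) {
    keys <- sprintf("ch%d_da%s_r%d", grid$channels[g],
                    if (grid$augmented[g]) "on" else "off", seq_len(repeats))
    s <- summarize_metrics(reports[keys])
    cbind(channels = grid$channels[g], augmented = grid$augmented[g], s)
  }))
  best <- lapply(seq_len(nrow(grid)), function(g) select_best(candidates[[g]]))
  names(best) <- sprintf("ch%d_da%s", grid$channels,
                         ifelse(grid$augmented, "on", "off"))
  structure(list(reports = reports, val_reports = val_reports,
                 summary = summary, best = best, grid = grid,
                 repeats = repeats, seed = seed),
            class = "holdout_result")
}

#' @export
print.holdout_result <- function(x, ...) {
  cat(sprintf("<holdout_result> %d repeats x %d grid cell(s)\n",
              x$repeats, nrow(x$grid)))
  print(x$summary, digits = 3)
  invisible(x)
}
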