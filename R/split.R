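# Participant-disjoint repeated hold-out splitting.

#' Randomly assign participants to train/validation/test roles
#'
#' Participants (never windows) are shuffled by seed and apportioned to the
#' three roles by largest-remainder counts, so subject-wise validity holds:
#' no participant contributes windows to more than one role. Ties in the
#' apportionment are broken toward the training set, then validation.
#'
#' @param ids character vector of at least 3 distinct participant IDs.
#' @param fractions train/validation/test proportions summing to 1
#'   (default `c(0.55, 0.25, 0.20)`).
#' @param seed integer seed for the shuffle.
#' @param repeat_index bookkeeping index of the hold-out repeat.
#' @return An object of class `split_spec` with `train_ids`, `val_ids`,
#'   `test_ids`.
#' @export
split_by_participant <- function(ids, fractions = c(0.55, 0.25, 0.20),
                                 seed = 1L, repeat_index = 1L) {
  ids <- as.character(ids)
  if (length(ids) < 3) iw_stop("need at least 3 participants to split", "split")
  if (anyDuplicated(ids)) iw_stop("participant IDs must be distinct", "split")
  if (length(fractions) != 3 || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-9)
    iw_stop("fractions must be 3 positive numbers summing to 1", "split")
  n <- length(ids)
  quota <- n * fractions
  counts <- floor(quota)
  left <- n - sum(counts)
  if (left > 0) {
    # largest remainder; ties toward train, then validation (stable order)
    rank <- order(quota - counts, -(1:3), decreasing = TRUE)
    counts[rank[seq_len(left)]] <- counts[rank[seq_len(left)]] + 1
  }
  shuffled <- with_seed(seed, sample(ids))
  structure(list(train_ids = shuffled[seq_len(counts[1])],
                 val_ids = shuffled[counts[1] + seq_len(counts[2])],
                 test_ids = shuffled[counts[1] + counts[2] + seq_len(counts[3])],
                 fractions = fractions,
                 seed = as.integer(seed),
                 repeat_index = as.integer(repeat_index)),
            class = "split_spec")
}

#' @export
print.split_spec <- function(x, ...) {
  cat(sprintf("<split_spec> repeat %d (seed %d): train %d | val %d | test %d participants\n",
              x$repeat_index, x$seed, length(x$train_ids), length(x$val_ids),
              length(x$test_ids)))
  invisible(x)
}

#' Partition recordings according to a split
#'
#' @param split a `split_spec` from [split_by_participant()].
#' @param recordings list of [imu_recording()] objects covering every ID in
#'   the split.
#' @return A list with elements `train`, `val`, `test`, each a list of
#'   recordings; every recording appears in exactly one element.
#' @export
materialize <- function(split, recordings) {
  stopifnot(inherits(split, "split_spec"))
  rec_ids <- vapply(recordings, `[[`, character(1), "participant_id")
  all_ids <- c(split$train_ids, split$val_ids, split$test_ids)
  missing <- setdiff(all_ids, rec_ids)
  if (length(missing))
    iw_stop(sprintf("split references unknown participant: %s", missing[1]),
            "consistency")
  pick <- function(ids) recordings[rec_ids %in% ids]
  list(train = pick(split$train_ids),
       val = pick(split$val_ids),
       test = pick(split$test_ids))
}
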