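activity_vocabulary <- c("walking", "walking with transitions", "shuffling",
                  "standing", "sitting", "transition", "leaning", "jumping",
                  "dynamic", "static", "lying", "shaking", "picking",
                  "kneeling", "stair ascending", "descending")

test_that("label binarization maps only the walking set to 1", {
  rec <- make_rec(T = 3, labels = c("walking", "sitting", "walking"))
  expect_equal(binarize_labels(rec), c(1L, 0L, 1L))

  # the full 16-activity vocabulary: only plain walking is positive
  rec16 <- make_rec(T = 16, labels = activity_vocabulary)
  expect_equal(binarize_labels(rec16), c(1L, rep(0L, 15)))

  # custom walking set
  als <- activity_label_set(c("walking", "shuffling"))
  expect_equal(sum(binarize_labels(rec16, als)), 2)

  rec0 <- make_rec(T = 4, labels = rep("sitting", 4))
  expect_equal(binarize_labels(rec0), rep(0L, 4))
})

test_that("segmentation produces the closed-form window count", {
  rec <- make_rec(T = 1000)
  ws <- segment(rec, window_len = 200, overlap = 0.5)
  expect_equal(n_windows(ws), 9)

  expect_equal(n_windows(segment(make_rec(T = 200))), 1)

  expect_warning(ws0 <- segment(make_rec(T = 150)), "shorter")
  expect_equal(n_windows(ws0), 0)

  # window contents equal the corresponding sample slice
  expect_equal(ws$windows[3, , ], rec$samples[201:400, ], ignore_attr = TRUE)
  expect_equal(ws$participant_ids, rep("P01", 9))
})

test_that("window label is the majority vote with ties to non-walking", {
  labs <- c(rep("walking", 100), rep("sitting", 100))
  rec <- make_rec(T = 200, labels = labs)
  expect_equal(segment(rec)$labels, 0L)  # exact tie -> non-walking

  labs2 <- c(rep("walking", 101), rep("sitting", 99))
  expect_equal(segment(make_rec(T = 200, labels = labs2))$labels, 1L)

  labs3 <- c(rep("walking", 99), rep("sitting", 101))
  expect_equal(segment(make_rec(T = 200, labels = labs3))$labels, 0L)
})

test_that("normalization centers every axis and is value-idempotent", {
  rec <- make_rec(T = 400)
  rec$samples[, 2] <- 7.5  # constant axis
  ws <- normalize_windows(segment(rec))
  m <- apply(ws$windows, c(1, 3), mean)
  expect_lt(max(abs(m)), 1e-9)
  expect_true(all(ws$windows[, , 2] == 0))
  expect_true(ws$normalized)

  # re-centering a centered window changes nothing numerically
  again <- ws
  again$normalized <- FALSE
  again <- normalize_windows(again)
  expect_equal(again$windows, ws$windows, tolerance = 1e-12)

  expect_error(normalize_windows(ws), class = "imuwalk_state_error")
})

test_that("quarter-turn rotation follows the right-handed convention", {
  v <- matrix(c(0, 0, 1), 1, 3)
  expect_equal(rotate90(v, "x", 1L), matrix(c(0, -1, 0), 1, 3))
  expect_equal(rotate90(v, "x", 0L), v)
  expect_equal(rotate90(v, "x", 4L), v)
  expect_error(rotate90(v, "x", 1.5), class = "imuwalk_argument_error")
  expect_error(rotate90(v, "w", 1L), class = "imuwalk_argument_error")
})

test_that("rotation applies identically to both triads of a recording", {
  rec <- make_rec(T = 100)
  rot <- rotate90(rec, "z", 1L)
  expect_equal(rot$samples[, 4:6],
               rotate90(rec$samples[, 4:6], "z", 1L), ignore_attr = TRUE)
  expect_equal(rot$samples[, 1:3],
               rotate90(rec$samples[, 1:3], "z", 1L), ignore_attr = TRUE)
  expect_identical(rot$labels, rec$labels)
})

test_that("augmentation adds one tagged copy per rotation", {
  ws <- random_ws(n = 10, W = 40, C = 6)
  out <- augment(ws)  # default: x, y, z quarter turns
  expect_equal(n_windows(out), 40)
  expect_equal(out$labels, rep(ws$labels, 4))
  expect_equal(out$participant_ids, rep(ws$participant_ids, 4))
  expect_equal(unique(out$augmented_from[11:40]), c("x+1", "y+1", "z+1"))
  # rotated copies really are rotations of the originals
  expect_equal(out$windows[11:20, , ], rotate90(ws, "x", 1L)$windows)

  expect_identical(augment(ws, list()), ws)
})

test_that("balancing down-samples the majority without fabrication", {
  ws <- random_ws(n = 13, W = 40, C = 3, seed = 8)
  ws$labels <- c(rep(1L, 3), rep(0L, 10))
  out <- balance_windows(ws, seed = 21)
  expect_equal(sum(out$labels == 1L), 3)
  expect_equal(sum(out$labels == 0L), 3)
  # retained non-walking windows are a subset of the originals
  orig_keys <- apply(ws$windows, 1, function(w) paste(signif(w), collapse = ","))
  out_keys <- apply(out$windows, 1, function(w) paste(signif(w), collapse = ","))
  expect_true(all(out_keys %in% orig_keys))
  # deterministic given the seed
  expect_identical(balance_windows(ws, seed = 21), out)

  balanced <- ws
  balanced$labels <- rep(c(0L, 1L), length.out = 13)[order(rep(1, 13))]
  balanced$labels <- c(rep(1L, 6), rep(0L, 6), 1L)
  ws_even <- subset_windows(balanced, 1:12)
  expect_identical(balance_windows(ws_even, seed = 3), ws_even)

  one_class <- ws
  one_class$labels <- rep(0L, 13)
  expect_error(balance_windows(one_class), class = "imuwalk_balance_error")
})

test_that("channel slicing keeps acceleration and drops gyroscope", {
  ws <- random_ws(n = 5, W = 40, C = 6)
  acc <- acc_only(ws)
  expect_equal(dim(acc$windows)[3], 3)
  expect_equal(acc$windows, ws$windows[, , 1:3, drop = FALSE])
  expect_identical(acc_only(acc), acc)
})
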