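test_that("confusion counts partition the windows", {
  expect_equal(confusion(c(1, 0, 1), c(1, 0, 1)),
               c(tp = 2, fp = 0, tn = 1, fn = 0))
  truth <- c(rep(1, 3), rep(0, 7))
  expect_equal(confusion(rep(0, 10), truth),
               c(tp = 0, fp = 0, tn = 7, fn = 3))
  expect_error(confusion(c(1, 0), c(1, 0, 1)),
               class = "imuwalk_argument_error")
  expect_error(confusion(integer(0), integer(0)),
               class = "imuwalk_argument_error")

  # brute-force oracle on random vectors
  set.seed(14)
  for (i in 1:10) {
    pred <- sample(0:1, 50, replace = TRUE)
    truth <- sample(0:1, 50, replace = TRUE)
    tally <- c(tp = 0, fp = 0, tn = 0, fn = 0)
    for (j in 1:50) {
      cell <- if (pred[j] == 1 && truth[j] == 1) "tp"
      else if (pred[j] == 1 && truth[j] == 0) "fp"
      else if (pred[j] == 0 && truth[j] == 0) "tn"
      else "fn"
      tally[cell] <- tally[cell] + 1
    }
    expect_equal(confusion(pred, truth), tally)
  }
})

test_that("the five metrics match their closed forms", {
  m <- metrics(8, 1, 9, 2)
  expect_equal(round(m$sensitivity, 3), 0.800)
  expect_equal(round(m$precision, 3), 0.889)
  expect_equal(round(m$specificity, 3), 0.900)
  expect_equal(round(m$accuracy, 3), 0.850)
  expect_equal(round(m$f1, 3), 0.842)
  expect_equal(m$n_windows, 20)
  expect_length(m$flags, 0)

  perfect <- metrics(5, 0, 5, 0)
  for (name in c("accuracy", "precision", "sensitivity", "f1", "specificity"))
    expect_equal(perfect[[name]], 1)

  # zero-denominator rule: no predicted positives
  degen <- metrics(0, 0, 7, 3)
  expect_equal(degen$precision, 0)
  expect_equal(degen$sensitivity, 0)
  expect_true(all(c("precision", "f1") %in% degen$flags))

  expect_error(metrics(0, 0, 0, 0), class = "imuwalk_argument_error")
  expect_error(metrics(-1, 0, 1, 0), class = "imuwalk_argument_error")

  # metrics() accepts the confusion() vector directly
  expect_equal(metrics(confusion(c(1, 0, 1), c(1, 0, 1)))$accuracy, 1)
})

test_that("rate metrics are integer-consistent with their counts", {
  set.seed(5)
  for (i in 1:20) {
    counts <- sample(0:40, 4, replace = TRUE)
    if (sum(counts) == 0) next
    m <- metrics(counts[1], counts[2], counts[3], counts[4])
    if (m$tp + m$fn > 0)
      expect_equal(m$sensitivity * (m$tp + m$fn), m$tp, tolerance = 1e-9)
    if (m$tn + m$fp > 0)
      expect_equal(m$specificity * (m$tn + m$fp), m$tn, tolerance = 1e-9)
    if (m$tp + m$fp > 0)
      expect_equal(m$precision * (m$tp + m$fp), m$tp, tolerance = 1e-9)
    expect_equal(m$accuracy * m$n_windows, m$tp + m$tn, tolerance = 1e-9)
  }
})

test_that("class ratio reports 1:r with r to two decimals", {
  expect_equal(class_ratio(15235, 131208)$label, "1:8.61")
  expect_equal(class_ratio(11271, 89139)$label, "1:7.91")
  expect_equal(class_ratio(10, 10)$label, "1:1.00")
  ws <- random_ws(n = 10, W = 40, C = 3)
  ws$labels <- c(rep(1L, 2), rep(0L, 8))
  expect_equal(class_ratio(ws)$r, 4)
  ws$labels <- rep(0L, 10)
  expect_error(class_ratio(ws), class = "imuwalk_ratio_error")
})

test_that("median(IQR) summaries follow the interpolated-quartile rule", {
  vals <- c(0.9, 0.92, 0.94, 0.96, 0.98)
  reports <- lapply(vals, function(v) {
    r <- metrics(8, 1, 9, 2)
    for (name in c("accuracy", "precision", "sensitivity", "f1",
                   "specificity")) r[[name]] <- v
    r
  })
  s <- summarize_metrics(reports)
  expect_equal(s$median, rep(0.94, 5))
  expect_equal(s$iqr, rep(0.05, 5))

  s1 <- summarize_metrics(reports[3])
  expect_equal(s1$median, rep(0.94, 5))
  expect_equal(s1$iqr, rep(0, 5))
})

test_that("best model selection maximizes sensitivity with F1 tie-breaks", {
  cand <- function(sens, f1, id) {
    m <- metrics(8, 1, 9, 2)
    m$sensitivity <- sens
    m$f1 <- f1
    list(model = id, metrics = m, repeat_index = id)
  }
  picked <- select_best(list(cand(0.91, 0.8, 1), cand(0.97, 0.8, 2),
                             cand(0.95, 0.9, 3)))
  expect_equal(picked$model, 2)

  expect_equal(select_best(list(cand(0.5, 0.5, 7)))$model, 7)

  tie <- select_best(list(cand(0.9, 0.80, 1), cand(0.9, 0.85, 2)))
  expect_equal(tie$model, 2)
  # full tie falls back to candidate order
  tie2 <- select_best(list(cand(0.9, 0.85, 1), cand(0.9, 0.85, 2)))
  expect_equal(tie2$model, 1)

  expect_error(select_best(list()), class = "imuwalk_argument_error")
})

test_that("repeated hold-out keeps the test pool untouched and reproduces", {
  recs <- simulate_dataset(tiny_synth_cfg(n = 4, duration = 120, seed = 19))
  mcfg <- tiny_model_cfg(window_len = 100, max_epochs = 2)
  res <- repeated_holdout(recs, repeats = 2, channels = 3, augmented = FALSE,
                          window_len = 100, model_cfg = mcfg, seed = 55)
  expect_length(res$reports, 2)
  for (r in res$reports) {
    expect_equal(r$tags$role, "test")
    expect_s3_class(r, "metrics_report")
    expect_equal(r$tp + r$fp + r$tn + r$fn, r$n_windows)
  }
  expect_equal(nrow(res$summary), 5)
  expect_s3_class(res$best[[1]]$metrics, "metrics_report")

  res2 <- repeated_holdout(recs, repeats = 2, channels = 3, augmented = FALSE,
                           window_len = 100, model_cfg = mcfg, seed = 55)
  expect_identical(res$summary, res2$summary)

  expect_error(repeated_holdout(recs, repeats = 0, window_len = 100,
                                model_cfg = mcfg),
               class = "imuwalk_argument_error")
})
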