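tiny_pipeline <- function(repeats = 2, seed = 9) {
  pipeline_config(synthetic = tiny_synth_cfg(n = 4, duration = 120, seed = 17),
                  window_len = 100,
                  model = tiny_model_cfg(window_len = 100, max_epochs = 2),
                  channels = c(3, 6), augmented = c(FALSE, TRUE),
                  repeats = repeats, seed = seed)
}

test_that("run_experiment writes a complete, traceable results directory", {
  out <- withr::local_tempdir()
  cfg <- tiny_pipeline()
  res <- run_experiment(cfg, out)

  expect_true(all(file.exists(file.path(out, c("manifest.tsv", "reports.tsv",
                                               "summary.tsv",
                                               "experiment.txt")))))
  reports <- read.delim(file.path(out, "reports.tsv"))
  # repeats x (channels x DA) grid, one test and one validation row each
  expect_equal(nrow(reports), 2 * 4 * 2)
  expect_setequal(unique(reports$cell),
                  c("ch3_daoff", "ch6_daoff", "ch3_daon", "ch6_daon"))
  expect_setequal(unique(reports$role), c("test", "validation"))

  manifest <- read.delim(file.path(out, "manifest.tsv"))
  expect_equal(nrow(manifest), 2 * 4)  # repeats x participants
  expect_setequal(unique(manifest$role), c("train", "val", "test"))

  summary <- read.delim(file.path(out, "summary.tsv"))
  expect_equal(nrow(summary), 4 * 5)  # cells x metrics
})

test_that("rerunning with the same seed reproduces results byte for byte", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  run_experiment(tiny_pipeline(), out1)
  run_experiment(tiny_pipeline(), out2)
  for (f in c("manifest.tsv", "reports.tsv", "summary.tsv"))
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
})

test_that("invalid pipeline configurations fail before any work", {
  expect_error(tiny_pipeline(repeats = 0), class = "imuwalk_config_error")
  expect_error(pipeline_config(window_len = 100,
                               model = tiny_model_cfg(window_len = 60)),
               class = "imuwalk_config_error")
  expect_error(pipeline_config(channels = c(2, 3)),
               class = "imuwalk_config_error")
})

test_that("the command-line dispatcher simulates and preprocesses", {
  cli <- system.file("cli", "imuwalk.R", package = "imuwalk")
  expect_true(nzchar(cli))
  out <- withr::local_tempdir()
  rscript <- file.path(R.home("bin"), "Rscript")

  status <- system2(rscript, c(cli, "simulate", "--participants", "2",
                               "--duration", "60", "--seed", "3",
                               "--out", out), stdout = TRUE, stderr = TRUE)
  files <- list.files(out, pattern = "^P.*\\.csv$")
  expect_length(files, 2)
  expect_true(file.exists(file.path(out, "manifest.tsv")))

  wfile <- file.path(out, "windows.rds")
  system2(rscript, c(cli, "preprocess", "--in", out, "--out", wfile,
                     "--window-len", "100"), stdout = TRUE, stderr = TRUE)
  ws <- read_windows(wfile)
  expect_s3_class(ws, "window_set")
  expect_equal(ws$window_len, 100)
  expect_setequal(unique(ws$participant_ids), c("P01", "P02"))
})
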