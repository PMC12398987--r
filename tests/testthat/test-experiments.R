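test_that("run seeds are deterministic, distinct across conditions, 32-bit", {
  s1 <- run_seed(1, "M0", 300, 1)
  expect_identical(s1, run_seed(1, "M0", 300, 1))
  grid <- expand.grid(arch = paste0("M", 0:5), n_cal = c(50, 300, 7000),
                      rep = 1:10, stringsAsFactors = FALSE)
  seeds <- mapply(run_seed, 1, grid$arch, grid$n_cal, grid$rep)
  expect_identical(anyDuplicated(seeds), 0L)
  expect_true(all(seeds >= 0 & seeds < 2^31))
  expect_false(run_seed(1, "M0", 300, 1) == run_seed(2, "M0", 300, 1))
})

test_that("the size sweep covers every condition exactly once", {
  col <- small_collection()
  res <- run_size_sweep(col, sizes = c(30L, 150L), reps = 2L, base_seed = 5,
                        config = fast_config(), arch = "M5",
                        keep_history = TRUE)
  expect_identical(nrow(res), 4L)
  expect_identical(anyDuplicated(res[, c("arch", "n_cal", "repetition")]), 0L)
  expect_true(all(res$stopped_epoch <= 12L))
  expect_true(all(res$exact_set_accuracy <= res$per_tooth_accuracy))
  expect_identical(length(attr(res, "histories")), 4L)

  # reruns with the same base seed reproduce the table
  res2 <- run_size_sweep(col, sizes = c(30L, 150L), reps = 2L, base_seed = 5,
                         config = fast_config(), arch = "M5")
  expect_identical(as.data.frame(res)[names(res2)], as.data.frame(res2))
})

test_that("training dynamics return complete histories per size", {
  col <- small_collection()
  dyn <- run_training_dynamics(col, sizes = c(20L, 150L), base_seed = 3,
                               config = fast_config(), arch = "M5")
  expect_identical(length(dyn$runs), 2L)
  for (r in dyn$runs) {
    expect_lte(r$stopped_epoch, 12L)
    expect_identical(nrow(r$history), r$stopped_epoch)
    expect_true(all(c("loss", "val_loss", "lr") %in% names(r$history)))
    expect_true(all(is.finite(r$history$loss)))
  }
  expect_error(run_training_dynamics(col, sizes = 10000L), "exceeds")
})

test_that("architecture comparison produces grouped results and stats", {
  col <- small_collection()
  res <- run_architecture_comparison(col, archs = c("M1", "M5"), n_cal = 40L,
                                     reps = 2L, base_seed = 9,
                                     config = fast_config())
  expect_identical(nrow(res), 4L)
  expect_setequal(unique(res$arch), c("M1", "M5"))
  cmp <- compare_groups(res)
  expect_identical(nrow(cmp$pairwise), 1L)
  expect_true(cmp$omnibus_p > 0 && cmp$omnibus_p <= 1)
})

test_that("summaries and exports are faithful to the tidy rows", {
  col <- small_collection()
  res <- run_size_sweep(col, sizes = c(30L, 150L), reps = 3L, base_seed = 7,
                        config = fast_config(), arch = "M5")
  sm <- summarize_runs(res)
  expect_identical(nrow(sm), 2L)
  for (r in seq_len(nrow(sm))) {
    rows <- res$exact_set_accuracy[res$n_cal == sm$n_cal[r]]
    expect_equal(sm$mean[r], mean(rows), tolerance = 1e-12)
    expect_equal(sm$sd[r], sd(rows), tolerance = 1e-12)
    expect_lte(sm$ci_lower[r], sm$mean[r])
    expect_gte(sm$ci_upper[r], sm$mean[r])
  }

  dir <- file.path(tempdir(), "exp-out")
  paths <- export_results(res, dir)
  back <- read.csv(paths[["runs"]])
  expect_equal(back$exact_set_accuracy, res$exact_set_accuracy,
               tolerance = 1e-12)
  back_sm <- read.csv(paths[["summary"]])
  expect_equal(back_sm$mean, sm$mean, tolerance = 1e-10)
  unlink(dir, recursive = TRUE)
})

test_that("manifests record provenance and leakage is detected", {
  dir <- file.path(tempdir(), "run-dir")
  col <- small_collection()
  train <- draw_ncal(col, 30, seed = 2)
  write_manifest(dir, "train", args = list(ncal = 30, seed = 2),
                 extra = list(train_case_ids = train$case_id))
  m <- read_manifest(dir)
  expect_identical(m$command, "train")
  expect_identical(sort(as.integer(unlist(m$train_case_ids))),
                   sort(train$case_id))

  test_cases <- collection_split(col, "test")
  expect_silent(check_leakage(dir, test_cases))
  expect_warning(check_leakage(dir, train), "data leakage")
  unlink(dir, recursive = TRUE)
})

test_that("the command-line tool plans and generates deterministically", {
  script <- system.file("scripts", "dentplan", package = "dentplan")
  skip_if(script == "", "script not installed")
  rscript <- file.path(R.home("bin"), "Rscript")

  out <- system2(rscript, c(script, "plan", "--findings",
                            shQuote(". . . . . . . . . . . . . . . .")),
                 stdout = TRUE)
  expect_identical(trimws(out[length(out)]),
                   paste(rep("-", 16), collapse = " "))

  d <- file.path(tempdir(), "cli-gen")
  dir.create(d, showWarnings = FALSE)
  f1 <- file.path(d, "a.csv"); f2 <- file.path(d, "b.csv")
  for (f in c(f1, f2))
    system2(rscript, c(script, "generate", "--n-total", "40", "--n-test",
                       "20", "--seed", "1", "--out", f), stdout = NULL)
  expect_identical(readLines(f1), readLines(f2))
  unlink(d, recursive = TRUE)
})
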