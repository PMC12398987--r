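# Experiment drivers: training dynamics at increasing N_cal, the
# N_cal-vs-accuracy learning curve, and the M0-M5 architecture comparison.
# Every run's seed derives deterministically from (base_seed, architecture,
# N_cal, repetition) so any single run can be reproduced in isolation.

ARCH_NAMES <- paste0("M", 0:5)

#' Derive the seed of one experimental run
#'
#' @param base_seed Integer base seed of the experiment.
#' @param arch Architecture name.
#' @param n_cal Training-set size of the run.
#' @param repetition Repetition index (1-based).
#' @return Integer seed below 2^31.
#' @export
run_seed <- function(base_seed, arch, n_cal, repetition) {
  a <- match(arch, ARCH_NAMES)
  if (is.na(a)) a <- 7L
  as.integer((as.numeric(base_seed) %% 100000 * 1000003 + a * 99991 +
              as.numeric(n_cal) * 101 + repetition * 13) %% 2147483647)
}

run_once <- function(collection, test_cases, arch, n_cal, repetition,
                     base_seed, config, keep_history = FALSE) {
  seed <- run_seed(base_seed, arch, n_cal, repetition)
  cases <- draw_ncal(collection, n_cal, seed)
  cfg <- config
  cfg$seed <- seed
  model <- train_model(build_model(arch, seed = seed), cases, cfg)
  ev <- evaluate_model(model, test_cases)
  row <- data.frame(arch = arch, n_cal = n_cal, repetition = repetition,
                    seed = seed,
                    exact_set_accuracy = ev$exact_set_accuracy,
                    per_tooth_accuracy = ev$per_tooth_accuracy,
                    stopped_epoch = model$stopped_epoch,
                    best_epoch = model$best_epoch,
                    stringsAsFactors = FALSE)
  list(row = row, history = if (keep_history) model$history, model = NULL)
}

#' Training dynamics at increasing training-set sizes
#'
#' Trains the baseline architecture once per size and returns the full
#' loss histories, mirroring the qualitative observation that larger
#' training sets converge in fewer epochs to lower losses.
#'
#' @param collection A `case_collection` whose training pool covers the
#'   largest size.
#' @param sizes Training-set sizes (N_cal values).
#' @param base_seed Integer base seed.
#' @param config A [training_config()].
#' @param arch Architecture preset (default `"M0"`).
#' @return A list of class `dynamics_runs`; one element per size with
#'   `n_cal`, `history`, `evaluation`, `stopped_epoch`, `best_epoch`.
#' @export
run_training_dynamics <- function(collection,
                                  sizes = c(10L, 100L, 1000L, 10000L),
                                  base_seed = 1L,
                                  config = training_config(),
                                  arch = "M0") {
  pool <- sum(collection$split == "trainpool")
  if (max(sizes) > pool)
    stop(sprintf("size %d exceeds the training pool (%d cases)",
                 max(sizes), pool), call. = FALSE)
  test_cases <- collection_split(collection, "test")
  runs <- lapply(sizes, function(sz) {
    seed <- run_seed(base_seed, arch, sz, 1L)
    cases <- draw_ncal(collection, sz, seed)
    cfg <- config
    cfg$seed <- seed
    model <- train_model(build_model(arch, seed = seed), cases, cfg)
    list(n_cal = sz, history = model$history,
         evaluation = evaluate_model(model, test_cases),
         stopped_epoch = model$stopped_epoch, best_epoch = model$best_epoch)
  })
  structure(list(runs = runs, sizes = sizes, arch = arch,
                 base_seed = base_seed),
            class = "dynamics_runs")
}

#' Learning-curve sweep over N_cal
#'
#' Trains the chosen architecture `reps` times per size, each repetition
#' with a fresh random draw of N_cal cases from the training pool and a
#' fresh initialization, and evaluates exact-set accuracy on the frozen
#' test pool.
#'
#' @param collection A `case_collection`.
#' @param sizes N_cal values to sweep.
#' @param reps Repetitions per size.
#' @param base_seed Integer base seed.
#' @param config A [training_config()].
#' @param arch Architecture preset.
#' @param keep_history Keep per-run loss histories (as an attribute).
#' @return A data frame of class `run_results` with one row per run:
#'   `arch`, `n_cal`, `repetition`, `seed`, `exact_set_accuracy`,
#'   `per_tooth_accuracy`, `stopped_epoch`, `best_epoch`.
#' @export
run_size_sweep <- function(collection, sizes, reps = 10L, base_seed = 1L,
                           config = training_config(), arch = "M0",
                           keep_history = FALSE) {
  test_cases <- collection_split(collection, "test")
  rows <- list()
  hist <- list()
  for (sz in sizes)
    for (r in seq_len(reps)) {
      res <- run_once(collection, test_cases, arch, sz, r, base_seed,
                      config, keep_history)
      rows[[length(rows) + 1L]] <- res$row
      if (keep_history)
        hist[[sprintf("%s_n%d_r%d", arch, sz, r)]] <- res$history
    }
  out <- do.call(rbind, rows)
  class(out) <- c("run_results", "data.frame")
  if (keep_history) attr(out, "histories") <- hist
  out
}

#' Architecture comparison at fixed N_cal
#'
#' Trains each architecture `reps` times at the same N_cal (fresh draws
#' and initializations per repetition) and evaluates on the test pool.
#'
#' @param collection A `case_collection`.
#' @param archs Architecture names.
#' @param n_cal Training-set size (default 300, where architectural
#'   differences are pronounced).
#' @param reps Repetitions per architecture.
#' @param base_seed Integer base seed.
#' @param config A [training_config()].
#' @return A `run_results` data frame (one row per run).
#' @export
run_architecture_comparison <- function(collection, archs = ARCH_NAMES,
                                        n_cal = 300L, reps = 10L,
                                        base_seed = 1L,
                                        config = training_config()) {
  test_cases <- collection_split(collection, "test")
  rows <- list()
  for (arch in archs)
    for (r in seq_len(reps)) {
      res <- run_once(collection, test_cases, arch, n_cal, r, base_seed,
                      config)
      rows[[length(rows) + 1L]] <- res$row
    }
  out <- do.call(rbind, rows)
  class(out) <- c("run_results", "data.frame")
  out
}

#' Summarize run results per condition
#'
#' @param results A `run_results` data frame.
#' @param conf_level Confidence level of the Student-t interval.
#' @return A data frame with one row per (arch, n_cal): `n`, `mean`, `sd`,
#'   `ci_lower`, `ci_upper` of exact-set accuracy.
#' @export
summarize_runs <- function(results, conf_level = 0.95) {
  sp <- split(results, list(results$arch, results$n_cal), drop = TRUE)
  rows <- lapply(sp, function(d) {
    x <- d$exact_set_accuracy
    n <- length(x)
    m <- mean(x)
    s <- stats::sd(x)
    half <- if (n > 1L) stats::qt(1 - (1 - conf_level) / 2, n - 1L) * s / sqrt(n)
            else NA_real_
    data.frame(arch = d$arch[1L], n_cal = d$n_cal[1L], n = n, mean = m,
               sd = s, ci_lower = m - half, ci_upper = m + half,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$arch, out$n_cal), ]
}

#' Export run results as tidy and summary CSV files
#'
#' @param results A `run_results` data frame.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths (`runs.csv`, `summary.csv`).
#' @export
export_results <- function(results, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  runs_path <- file.path(dir, "runs.csv")
  summary_path <- file.path(dir, "summary.csv")
  utils::write.csv(as.data.frame(results), runs_path, row.names = FALSE)
  utils::write.csv(summarize_runs(results), summary_path, row.names = FALSE)
  invisible(c(runs = runs_path, summary = summary_path))
}

#' Box plot of an architecture comparison
#'
#' @param results A `run_results` data frame from
#'   [run_architecture_comparison()].
#' @param ... Passed to [graphics::boxplot()].
#' @export
plot_comparison <- function(results, ...) {
  graphics::boxplot(exact_set_accuracy ~ arch, data = results,
                    xlab = "architecture", ylab = "exact-set accuracy (%)",
                    ...)
  invisible(results)
}
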