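# The plan_net model object: a sequence-labelling network over findings
# charts, fitted with the fixed training protocol and scored against the
# rule engine.

encode_findings_matrix <- function(fmat) {
  m <- matrix(match(fmat, FINDING_SYMBOLS) - 1L, nrow = nrow(fmat))
  if (anyNA(m)) stop("unknown finding symbol in case matrix", call. = FALSE)
  storage.mode(m) <- "integer"
  m
}

encode_plan_matrix <- function(pmat) {
  m <- matrix(match(pmat, PLAN_SYMBOLS) - 1L, nrow = nrow(pmat))
  if (anyNA(m)) stop("unknown plan symbol in case matrix", call. = FALSE)
  storage.mode(m) <- "integer"
  m
}

#' Build an untrained planning network
#'
#' Instantiates one of the architecture presets with seed-controlled
#' weight initialization (uniform embedding, Glorot-uniform dense and
#' input kernels, orthogonal recurrent kernels, unit forget-gate bias).
#'
#' @param arch An [architecture_spec()] or preset name `"M0"`..`"M5"`.
#' @param seed Integer seed for the weight draw.
#' @return An object of class `plan_net` (untrained).
#' @export
#' @examples
#' m <- build_model("M5", seed = 1)
#' m
build_model <- function(arch = "M0", seed = 1L) {
  if (!inherits(arch, "architecture_spec")) arch <- architecture_spec(arch)
  weights <- cpp_init_weights(arch$layers, length(FINDING_SYMBOLS),
                              as.integer(seed))
  structure(list(arch = arch, weights = weights, seed = as.integer(seed),
                 trained = FALSE, history = NULL),
            class = "plan_net")
}

#' Train a planning network on a case collection
#'
#' Applies the study protocol: the cases are split 80/20 into training and
#' validation under the configuration seed, the network is fitted with
#' Adam under categorical cross-entropy in minibatches of 32, the learning
#' rate is halved after 5 epochs without validation-loss improvement down
#' to 1e-7, and training stops after 10 epochs without improvement (best
#' weights restored) or at 200 epochs.
#'
#' @param model A `plan_net` from [build_model()].
#' @param cases A `case_collection` with at least 10 cases.
#' @param config A [training_config()].
#' @return The trained `plan_net`, with a `history` data frame (`epoch`,
#'   `loss`, `val_loss`, `lr`) and elements `best_epoch`, `stopped_epoch`,
#'   `n_train`, `n_val`.
#' @export
train_model <- function(model, cases, config = training_config()) {
  stopifnot(inherits(model, "plan_net"), inherits(cases, "case_collection"),
            inherits(config, "training_config"))
  n <- n_cases(cases)
  if (n < 10L)
    stop(sprintf("training needs at least 10 cases, got %d", n),
         call. = FALSE)
  X <- encode_findings_matrix(cases$findings)
  Y <- encode_plan_matrix(cases$plans)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(config$seed)
  n_val <- max(1L, as.integer(round(config$val_fraction * n)))
  vidx <- resample(seq_len(n), n_val)
  tidx <- setdiff(seq_len(n), vidx)

  res <- cpp_train(model$arch$layers, model$weights,
                   X[tidx, , drop = FALSE], Y[tidx, , drop = FALSE],
                   X[vidx, , drop = FALSE], Y[vidx, , drop = FALSE],
                   unclass(config), length(FINDING_SYMBOLS), config$seed)
  model$weights <- res$weights
  model$trained <- TRUE
  model$history <- data.frame(epoch = seq_along(res$train_loss),
                              loss = res$train_loss,
                              val_loss = res$val_loss,
                              lr = res$lr)
  model$best_epoch <- res$best_epoch
  model$stopped_epoch <- res$stopped_epoch
  model$best_val_loss <- res$best_val_loss
  model$n_train <- length(tidx)
  model$n_val <- n_val
  model$config <- config
  model
}

#' Fit a planning network in one call
#'
#' Convenience wrapper: [build_model()] then [train_model()], both driven
#' by the configuration seed.
#'
#' @param cases A `case_collection`.
#' @param arch Architecture preset name or [architecture_spec()].
#' @param config A [training_config()].
#' @return A trained `plan_net`.
#' @export
plan_net <- function(cases, arch = "M0", config = training_config()) {
  train_model(build_model(arch, seed = config$seed), cases, config)
}

# Row-stochastic predictions for an integer-encoded findings matrix,
# as an n x 16 x 4 array.
predict_probs <- function(model, X) {
  stopifnot(inherits(model, "plan_net"))
  cpp_forward(model$arch$layers, model$weights, X,
              length(FINDING_SYMBOLS))
}

#' Predict plan charts
#'
#' @param object A `plan_net`.
#' @param newdata A findings chart (vector or string), a character matrix
#'   of charts (one per row), or a `case_collection`.
#' @param type `"chart"` for decoded plan charts, `"prob"` for the raw
#'   n x 16 x 4 probability array.
#' @param ... Unused.
#' @return A `plan_chart` (single chart), a character matrix of plan
#'   tokens, or the probability array.
#' @export
predict.plan_net <- function(object, newdata, type = c("chart", "prob"), ...) {
  type <- match.arg(type)
  single <- FALSE
  if (inherits(newdata, "case_collection")) {
    fmat <- newdata$findings
  } else if (is.matrix(newdata)) {
    fmat <- newdata
  } else {
    fmat <- matrix(as_findings(newdata), nrow = 1L)
    single <- TRUE
  }
  probs <- predict_probs(object, encode_findings_matrix(fmat))
  if (type == "prob") return(probs)
  n <- nrow(fmat)
  flat <- matrix(probs, nrow = n * N_TEETH, ncol = length(PLAN_SYMBOLS))
  idx <- max.col(flat, ties.method = "first")
  pm <- matrix(PLAN_SYMBOLS[idx], nrow = n, ncol = N_TEETH)
  if (single)
    structure(pm[1L, ], class = c("plan_chart", "dental_chart"))
  else pm
}

#' Predict the plan for a single findings chart
#'
#' @param model A trained `plan_net`.
#' @param findings A findings chart (16 tokens or one string).
#' @return A `plan_chart`.
#' @export
predict_plan <- function(model, findings) {
  predict(model, findings)
}

# Accuracy arithmetic shared by evaluate_model and the tests: predictions
# and truth as n x 16 integer class matrices.
evaluate_predictions <- function(pred, truth) {
  stopifnot(is.matrix(pred), is.matrix(truth),
            all(dim(pred) == dim(truth)), nrow(pred) >= 1L)
  n <- nrow(pred)
  exact <- mean(rowSums(pred == truth) == ncol(pred))
  per_tooth <- mean(pred == truth)
  lev <- seq_along(PLAN_SYMBOLS) - 1L
  confusion <- table(truth = factor(truth, levels = lev,
                                    labels = PLAN_SYMBOLS),
                     predicted = factor(pred, levels = lev,
                                        labels = PLAN_SYMBOLS))
  structure(list(exact_set_accuracy = 100 * exact,
                 per_tooth_accuracy = 100 * per_tooth,
                 n_cases = n, confusion = confusion),
            class = "plan_eval")
}

#' Evaluate a planning network against labelled cases
#'
#' Exact-set accuracy is the percentage of cases whose predicted plan
#' matches the labelled plan at all 16 positions; per-tooth accuracy is
#' the percentage of correctly planned positions.
#'
#' @param model A trained `plan_net`.
#' @param cases A non-empty `case_collection`.
#' @return An object of class `plan_eval` with `exact_set_accuracy`,
#'   `per_tooth_accuracy`, `n_cases` and a 4 x 4 per-tooth `confusion`
#'   table over the plan codes.
#' @export
evaluate_model <- function(model, cases) {
  stopifnot(inherits(cases, "case_collection"))
  if (n_cases(cases) < 1L) stop("empty case set", call. = FALSE)
  pm <- predict(model, cases)
  evaluate_predictions(encode_plan_matrix(pm),
                       encode_plan_matrix(cases$plans))
}

#' @export
print.plan_eval <- function(x, ...) {
  cat(sprintf("<plan_eval> %d cases: exact-set %.2f%%, per-tooth %.2f%%\n",
              x$n_cases, x$exact_set_accuracy, x$per_tooth_accuracy))
  invisible(x)
}

#' Number of trainable parameters
#' @param model A `plan_net`.
#' @return Numeric parameter count.
#' @export
n_params <- function(model) {
  stopifnot(inherits(model, "plan_net"))
  cpp_count_params(model$weights)
}

#' @export
print.plan_net <- function(x, ...) {
  cat(sprintf("<plan_net %s> %s, %s parameters\n", x$arch$name,
              if (x$trained) "trained" else "untrained",
              format(n_params(x), big.mark = ",")))
  if (x$trained)
    cat(sprintf("  %d epochs (best %d), best validation loss %.4f on %d cases\n",
                x$stopped_epoch, x$best_epoch, x$best_val_loss, x$n_val))
  invisible(x)
}

#' @export
summary.plan_net <- function(object, ...) {
  print(object$arch)
  print(object)
  if (object$trained) {
    cat(sprintf("  trained on %d cases (+%d validation), final lr %.2e\n",
                object$n_train, object$n_val,
                object$history$lr[nrow(object$history)]))
  }
  invisible(object)
}

#' @export
coef.plan_net <- function(object, ...) object$weights

#' Plot training history
#'
#' Training and validation loss against epochs, with the best epoch
#' marked.
#'
#' @param x A trained `plan_net`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.plan_net <- function(x, ...) {
  if (!x$trained) stop("model is untrained; nothing to plot", call. = FALSE)
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$loss, h$val_loss), type = "l",
                    lty = 1, col = c("black", "firebrick"),
                    xlab = "epoch", ylab = "categorical cross-entropy",
                    main = sprintf("%s training dynamics", x$arch$name), ...)
  graphics::abline(v = x$best_epoch, lty = 3, col = "grey40")
  graphics::legend("topright", c("training loss", "validation loss"),
                   lty = 1, col = c("black", "firebrick"), bty = "n")
  invisible(x)
}
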