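# The six studied architectures. All map a 16-token findings chart to a
# 16 x 4 row-stochastic matrix over the plan codes. M0 is the baseline:
#   Embedding(64) > BiLSTM(128/dir) > Dropout(0.5) > Dense(64, relu)
#     > Dropout(0.5) > Dense(4, softmax)
# M1 swaps the LSTM for a position-wise dense layer of 128 (destroying all
# cross-tooth information flow), M2 adds Dense(32)+Dropout, M3 drops the
# Dense(64), M4 doubles and M5 halves every layer width (embedding
# included; recurrent widths are per direction).

layer <- function(type, ...) c(list(type = type), list(...))

arch_presets <- function() {
  dense_relu <- function(u) layer("dense", units = u, activation = "relu")
  drop <- layer("dropout", rate = 0.5)
  out <- layer("dense", units = 4L, activation = "softmax")
  stack <- function(emb, lstm, dense_widths, lstm_is_dense = FALSE) {
    layers <- list(layer("embedding", units = emb))
    layers <- c(layers, list(
      if (lstm_is_dense) dense_relu(lstm) else layer("bilstm", units = lstm),
      drop))
    for (u in dense_widths) layers <- c(layers, list(dense_relu(u), drop))
    c(layers, list(out))
  }
  list(
    M0 = stack(64L, 128L, 64L),
    M1 = stack(64L, 128L, 64L, lstm_is_dense = TRUE),
    M2 = stack(64L, 128L, c(64L, 32L)),
    M3 = stack(64L, 128L, integer(0)),
    M4 = stack(128L, 256L, 128L),
    M5 = stack(32L, 64L, 32L)
  )
}

#' Architecture specification
#'
#' Returns the declarative layer stack of one of the six named presets
#' M0..M5, or wraps a custom layer list.
#'
#' @param name One of `"M0"`..`"M5"`, or a list of layer descriptions
#'   (each a list with `type` and, as applicable, `units`, `rate`,
#'   `activation`).
#' @return An object of class `architecture_spec` with elements `name`
#'   and `layers`.
#' @export
#' @examples
#' architecture_spec("M0")
architecture_spec <- function(name = "M0") {
  if (is.list(name))
    return(structure(list(name = "custom", layers = name),
                     class = "architecture_spec"))
  presets <- arch_presets()
  if (!name %in% names(presets))
    stop(sprintf("unknown architecture '%s'; available: %s", name,
                 paste(names(presets), collapse = ", ")), call. = FALSE)
  structure(list(name = name, layers = presets[[name]]),
            class = "architecture_spec")
}

#' @export
print.architecture_spec <- function(x, ...) {
  fmt <- vapply(x$layers, function(l) {
    switch(l$type,
           embedding = sprintf("Embedding(%d)", l$units),
           bilstm = sprintf("BiLSTM(%d/dir)", l$units),
           dense = sprintf("Dense(%d, %s)", l$units, l$activation),
           dropout = sprintf("Dropout(%.1f)", l$rate))
  }, character(1))
  cat(sprintf("<architecture_spec %s> %s\n", x$name,
              paste(fmt, collapse = " > ")))
  invisible(x)
}

#' Training protocol configuration
#'
#' Defaults encode the study protocol: Adam with initial learning rate
#' 1e-3, halved after 5 epochs without validation-loss improvement down to
#' a floor of 1e-7; early stopping after 10 epochs without improvement
#' with the best weights restored; at most 200 epochs; batch size 32; an
#' inner 80/20 train/validation split.
#'
#' @param initial_lr Initial Adam learning rate.
#' @param lr_factor Multiplicative learning-rate reduction on plateau.
#' @param lr_patience Plateau length (epochs) triggering a reduction.
#' @param lr_floor Minimum learning rate.
#' @param early_stop_patience Epochs without validation improvement before
#'   stopping.
#' @param restore_best Restore the weights of the best validation epoch.
#' @param max_epochs Hard epoch cap.
#' @param batch_size Minibatch size.
#' @param val_fraction Fraction of the N_cal cases held out for validation.
#' @param seed Integer seed controlling the inner split, shuffling and
#'   dropout.
#' @return An object of class `training_config`.
#' @export
training_config <- function(initial_lr = 1e-3, lr_factor = 0.5,
                            lr_patience = 5L, lr_floor = 1e-7,
                            early_stop_patience = 10L, restore_best = TRUE,
                            max_epochs = 200L, batch_size = 32L,
                            val_fraction = 0.2, seed = 1L) {
  cfg <- list(initial_lr = initial_lr, lr_factor = lr_factor,
              lr_patience = as.integer(lr_patience), lr_floor = lr_floor,
              early_stop_patience = as.integer(early_stop_patience),
              restore_best = isTRUE(restore_best),
              max_epochs = as.integer(max_epochs),
              batch_size = as.integer(batch_size),
              val_fraction = val_fraction, seed = as.integer(seed))
  if (cfg$val_fraction <= 0 || cfg$val_fraction >= 1)
    stop("val_fraction must lie strictly between 0 and 1", call. = FALSE)
  if (cfg$max_epochs < 1L || cfg$batch_size < 1L)
    stop("max_epochs and batch_size must be positive", call. = FALSE)
  structure(cfg, class = "training_config")
}
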