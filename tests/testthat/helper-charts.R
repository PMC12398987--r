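# Shared test helpers: quick chart construction and a cached small case
# collection so the expensive generation runs once per test session.

# chart_at(`5` = "k", `6` = "b", `7` = "k") -> findings vector with the
# named positions substituted into an all-sufficient chart
chart_at <- function(...) {
  subs <- list(...)
  ch <- rep(".", 16L)
  for (nm in names(subs)) ch[as.integer(nm)] <- subs[[nm]]
  ch
}

.cache <- new.env(parent = emptyenv())

# 600 cases (300 train / 300 test), enough for light training runs
small_collection <- function() {
  if (is.null(.cache$small))
    .cache$small <- generate_collection(
      generator_config(n_total = 600L, n_test = 300L, seed = 101L))
  .cache$small
}

# quick training protocol for unit tests (protocol contracts are tested
# separately at the full defaults)
fast_config <- function(seed = 1L, max_epochs = 12L) {
  training_config(seed = seed, max_epochs = max_epochs)
}

# tiny custom architecture for protocol tests: full layer variety, few
# parameters
tiny_arch <- function() {
  architecture_spec(list(
    list(type = "embedding", units = 8L),
    list(type = "bilstm", units = 8L),
    list(type = "dropout", rate = 0.5),
    list(type = "dense", units = 8L, activation = "relu"),
    list(type = "dropout", rate = 0.5),
    list(type = "dense", units = 4L, activation = "softmax")))
}
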