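# Constrained generator of valid, unique, rule-labelled synthetic case
# collections. Generation is constructive: removable dentures, gaps,
# bridges, crowns and carious teeth are placed so that the structural
# rules R1-R3 hold by construction; a bounded rejection loop enforces the
# fixed-bridge quota on every second case.

# sample() semantics are unsafe for length-1 x; always index explicitly.
resample <- function(x, size = length(x)) x[sample.int(length(x), size)]

#' Configuration of the synthetic case generator
#'
#' Collects the counts, split size, seed and nuisance distribution
#' parameters of one generation run. The defaults are the study
#' conditions: 20,000 unique cases, half reserved as a frozen test pool,
#' and per-appliance insufficiency, denture-presence, crown and
#' carious-tooth rates chosen so that all ten finding codes occur with
#' non-negligible frequency.
#'
#' @param n_total Total number of unique cases to generate.
#' @param n_test Number of cases frozen into the held-out test pool.
#' @param seed Integer seed; generation is fully deterministic given the
#'   configuration.
#' @param max_missing Maximum number of missing/condemned teeth per chart
#'   (count drawn uniformly on 0..`max_missing`).
#' @param p_insufficient Probability that a placed appliance (bridge,
#'   crown, denture) is insufficient; applied per appliance so that
#'   sufficiency stays uniform within it.
#' @param p_rdp_present Probability that a chart carries an existing
#'   removable denture.
#' @param p_ww Per-tooth probability of an insufficient but
#'   preservation-worthy natural tooth.
#' @param p_crown Per-tooth probability of a standalone crown.
#' @param p_complete_denture Probability, given a denture is present, that
#'   it is a complete denture (all 16 teeth replaced) rather than a
#'   partial one.
#' @param max_rdp_teeth Maximum number of teeth replaced by a partial
#'   denture (count drawn uniformly on 2..`max_rdp_teeth`).
#' @param max_bridges Maximum number of existing bridges placed per chart.
#' @param max_pontics Maximum pontic-run length of a placed bridge.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_total = 20000L, n_test = 10000L, seed = 1L,
                             max_missing = 10L, p_insufficient = 0.5,
                             p_rdp_present = 0.3, p_ww = 0.1,
                             p_crown = 0.08, p_complete_denture = 0.2,
                             max_rdp_teeth = 8L, max_bridges = 2L,
                             max_pontics = 3L) {
  cfg <- list(n_total = as.integer(n_total), n_test = as.integer(n_test),
              seed = as.integer(seed), max_missing = as.integer(max_missing),
              p_insufficient = p_insufficient,
              p_rdp_present = p_rdp_present, p_ww = p_ww, p_crown = p_crown,
              p_complete_denture = p_complete_denture,
              max_rdp_teeth = as.integer(max_rdp_teeth),
              max_bridges = as.integer(max_bridges),
              max_pontics = as.integer(max_pontics))
  if (cfg$n_total < 1L) stop("n_total must be positive", call. = FALSE)
  if (cfg$n_test < 0L || cfg$n_test >= cfg$n_total)
    stop("n_test must satisfy 0 <= n_test < n_total", call. = FALSE)
  probs <- c(cfg$p_insufficient, cfg$p_rdp_present, cfg$p_ww, cfg$p_crown,
             cfg$p_complete_denture)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (cfg$max_rdp_teeth < 2L || cfg$max_rdp_teeth > N_TEETH)
    stop("max_rdp_teeth must lie in 2..16", call. = FALSE)
  structure(cfg, class = "generator_config")
}

# Maximal runs of TRUE in a logical vector, as a start/end data frame.
logical_runs <- function(ok) {
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

# One constructive draw of a findings chart. Valid by construction except
# for rare interactions, which the caller rejects.
build_chart <- function(config) {
  ch <- rep(".", N_TEETH)
  free <- rep(TRUE, N_TEETH)       # position still holds a plain "."
  blocked <- rep(FALSE, N_TEETH)   # buffer next to a placed bridge

  # existing removable denture: complete or partial, uniformly
  # (in)sufficient; wisdom teeth are never replaced, so they never carry
  # denture teeth
  if (stats::runif(1) < config$p_rdp_present) {
    non_wisdom <- setdiff(seq_len(N_TEETH), WISDOM_POSITIONS)
    pos <- if (stats::runif(1) < config$p_complete_denture) {
      non_wisdom
    } else {
      n_rdp <- sample.int(config$max_rdp_teeth - 1L, 1L) + 1L  # 2..max
      resample(non_wisdom, n_rdp)
    }
    ch[pos] <- if (stats::runif(1) < config$p_insufficient) "ew" else "e"
    free[pos] <- FALSE
  }

  # missing / condemned teeth
  avail <- which(free)
  if (length(avail)) {
    n_miss <- sample.int(min(config$max_missing, length(avail)) + 1L, 1L) - 1L
    if (n_miss > 0L) {
      pos <- resample(avail, n_miss)
      ch[pos] <- ifelse(stats::runif(n_miss) < 0.5, "f", "x")
      free[pos] <- FALSE
    }
  }

  # existing bridges: abutment crowns flanking a pontic run, sufficiency
  # uniform per bridge; a one-position buffer keeps later crowns/bridges
  # from merging into the block and breaking uniformity
  n_bridges <- sample.int(config$max_bridges + 1L, 1L) - 1L
  for (i in seq_len(n_bridges)) {
    runs <- logical_runs(free & !blocked)
    runs <- runs[runs$end - runs$start + 1L >= 3L, , drop = FALSE]
    if (!nrow(runs)) break
    j <- sample.int(nrow(runs), 1L)
    len <- runs$end[j] - runs$start[j] + 1L
    n_pontics <- sample.int(min(config$max_pontics, len - 2L), 1L)
    span_len <- n_pontics + 2L
    st <- runs$start[j] + sample.int(len - span_len + 1L, 1L) - 1L
    insuff <- stats::runif(1) < config$p_insufficient
    ch[c(st, st + span_len - 1L)] <- if (insuff) "kw" else "k"
    ch[(st + 1L):(st + span_len - 2L)] <- if (insuff) "bw" else "b"
    free[st:(st + span_len - 1L)] <- FALSE
    blocked[max(1L, st - 1L)] <- TRUE
    blocked[min(N_TEETH, st + span_len)] <- TRUE
  }

  # standalone crowns, then preservation-worthy carious teeth
  avail <- which(free & !blocked)
  if (length(avail)) {
    is_crown <- stats::runif(length(avail)) < config$p_crown
    cr <- avail[is_crown]
    if (length(cr))
      ch[cr] <- ifelse(stats::runif(length(cr)) < config$p_insufficient,
                       "kw", "k")
    rest <- avail[!is_crown]
    if (length(rest)) {
      w <- rest[stats::runif(length(rest)) < config$p_ww]
      ch[w] <- "ww"
    }
  }
  ch
}

#' Sample one valid findings chart
#'
#' Draws a chart from the generator's constructive distribution. The
#' returned chart always passes [validate_findings()] with zero
#' violations; with `force_fdp = TRUE` a bounded rejection loop guarantees
#' that [plan_case()] of the chart contains at least one bridge unit.
#' Consumes the R random number stream; seed with `set.seed()`.
#'
#' @param config A [generator_config()].
#' @param force_fdp Require the resulting plan to contain a `B`.
#' @param max_attempts Rejection budget before erroring (a mis-tuned
#'   configuration is the only way to exhaust it).
#' @return A `findings_chart` with the matching plan attached as attribute
#'   `plan`.
#' @export
sample_findings <- function(config = generator_config(), force_fdp = FALSE,
                            max_attempts = 10000L) {
  for (attempt in seq_len(max_attempts)) {
    ch <- build_chart(config)
    if (nrow(validate_findings(ch))) next
    pl <- plan_case(ch, check = FALSE)
    if (!force_fdp || plan_contains_fdp(pl))
      return(structure(ch, class = c("findings_chart", "dental_chart"),
                       plan = pl))
  }
  stop(sprintf(
    "no admissible chart found in %d attempts; generator configuration %s",
    max_attempts,
    if (force_fdp) "cannot produce bridge-containing plans" else "is mis-tuned"),
    call. = FALSE)
}

#' Generate a labelled case collection
#'
#' Produces `n_total` unique findings charts with their rule-engine plans.
#' Every second case (even generation ranks) is forced to include a fixed
#' bridge in its plan, which keeps bridges well represented; duplicates
#' are resampled in place so the forcing parity is preserved. `n_test`
#' cases are then drawn uniformly at random into a frozen test pool; the
#' remainder form the training pool.
#'
#' @param config A [generator_config()].
#' @return An object of class `case_collection`: a list with character
#'   matrices `findings` and `plans` (one row per case, 16 columns),
#'   `case_id`, `split` (`"trainpool"`/`"test"`) and `config`.
#' @export
#' @examples
#' col <- generate_collection(generator_config(n_total = 30, n_test = 10))
#' col
generate_collection <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(config$seed)

  n <- config$n_total
  fmat <- matrix("", n, N_TEETH)
  pmat <- matrix("", n, N_TEETH)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  for (rank in seq_len(n)) {
    force_fdp <- rank %% 2L == 0L
    for (attempt in seq_len(10000L)) {
      ch <- sample_findings(config, force_fdp = force_fdp)
      key <- paste(ch, collapse = "")
      if (is.null(seen[[key]])) break
      if (attempt == 10000L)
        stop("unique-chart space exhausted under this configuration",
             call. = FALSE)
    }
    seen[[key]] <- TRUE
    fmat[rank, ] <- as.character(ch)
    pmat[rank, ] <- as.character(attr(ch, "plan"))
  }
  split <- rep("trainpool", n)
  split[resample(seq_len(n), config$n_test)] <- "test"
  structure(list(findings = fmat, plans = pmat, case_id = seq_len(n),
                 split = split, config = config),
            class = "case_collection")
}

#' Number of cases in a collection
#' @param collection A `case_collection`.
#' @return Integer count.
#' @export
n_cases <- function(collection) nrow(collection$findings)

#' Subset a case collection by row index
#'
#' @param collection A `case_collection`.
#' @param idx Integer row indices.
#' @return A `case_collection` restricted to the selected cases.
#' @export
subset_cases <- function(collection, idx) {
  structure(list(findings = collection$findings[idx, , drop = FALSE],
                 plans = collection$plans[idx, , drop = FALSE],
                 case_id = collection$case_id[idx],
                 split = collection$split[idx],
                 config = collection$config),
            class = "case_collection")
}

#' Cases of one split
#' @param collection A `case_collection`.
#' @param split `"trainpool"` or `"test"`.
#' @return A `case_collection` holding only that split.
#' @export
collection_split <- function(collection, split = c("trainpool", "test")) {
  split <- match.arg(split)
  subset_cases(collection, which(collection$split == split))
}

#' Draw a training subset of size N_cal
#'
#' Samples `n_cal` cases uniformly at random from the training pool only;
#' the frozen test pool is never touched.
#'
#' @param collection A `case_collection`.
#' @param n_cal Number of cases to draw.
#' @param seed Integer seed for the draw.
#' @return A `case_collection` of `n_cal` training-pool cases.
#' @export
draw_ncal <- function(collection, n_cal, seed) {
  pool <- which(collection$split == "trainpool")
  if (n_cal > length(pool))
    stop(sprintf("n_cal = %d exceeds the training pool size %d",
                 n_cal, length(pool)), call. = FALSE)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  subset_cases(collection, resample(pool, n_cal))
}

#' @export
print.case_collection <- function(x, ...) {
  fdp <- mean(apply(x$plans == "B", 1L, any))
  seed_txt <- if (is.null(x$config)) "unknown seed"
              else sprintf("seed %d", x$config$seed)
  cat(sprintf("<case_collection> %d cases (%d trainpool / %d test), %s\n",
              n_cases(x), sum(x$split == "trainpool"), sum(x$split == "test"),
              seed_txt))
  cat(sprintf("  plans containing a bridge: %.1f%%\n", 100 * fdp))
  invisible(x)
}

#' @export
summary.case_collection <- function(object, ...) {
  ft <- table(factor(object$findings, levels = FINDING_SYMBOLS))
  pt <- table(factor(object$plans, levels = PLAN_SYMBOLS))
  out <- list(n = n_cases(object),
              split = table(object$split),
              finding_frequencies = ft / sum(ft),
              plan_frequencies = pt / sum(pt),
              fdp_fraction = mean(apply(object$plans == "B", 1L, any)))
  class(out) <- "summary.case_collection"
  out
}

#' @export
print.summary.case_collection <- function(x, ...) {
  cat(sprintf("case collection with %d cases\n", x$n))
  print(x$split)
  cat("finding symbol frequencies:\n")
  print(round(x$finding_frequencies, 4))
  cat("plan symbol frequencies:\n")
  print(round(x$plan_frequencies, 4))
  cat(sprintf("fraction of plans containing a bridge: %.3f\n", x$fdp_fraction))
  invisible(x)
}
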