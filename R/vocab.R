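# Finding and plan vocabularies. The integer index tables are fixed by the
# row order below (0-based) and are serialized with every dataset file so
# that encoded artifacts stay byte-reproducible.

FINDING_SYMBOLS <- c("f", ".", "x", "k", "b", "e", "ww", "kw", "bw", "ew")

FINDING_MEANINGS <- c(
  "missing tooth, not replaced by FDP or RDP",
  "tooth, sufficient",
  "tooth to be extracted (condemned)",
  "crown, sufficient (FDP)",
  "bridge unit, sufficient (FDP)",
  "replaced tooth with RDP, sufficient",
  "insufficient natural tooth (e.g. carious lesion), preservation worthy",
  "insufficient crown, renewal required (FDP)",
  "insufficient bridge unit, renewal required (FDP)",
  "insufficiently replaced tooth with RDP, renewal required"
)

PLAN_SYMBOLS <- c("-", "K", "B", "E")

PLAN_MEANINGS <- c(
  "no dental prosthesis required",
  "crown",
  "bridge unit",
  "tooth to be replaced with RDP"
)

N_TEETH <- 16L
WISDOM_POSITIONS <- c(1L, 16L)

# FDI two-digit labels for one (upper) jaw, attached for display only; all
# planning rules operate on abstract positions 1..16.
FDI_LABELS <- c("18", "17", "16", "15", "14", "13", "12", "11",
                "21", "22", "23", "24", "25", "26", "27", "28")

#' Finding vocabulary
#'
#' The ten per-tooth finding codes with their fixed 0-based integer indices.
#' The index table is part of the package contract: encoded datasets and
#' model inputs use these indices, and [write_collection()] serializes the
#' table alongside every case file.
#'
#' @return A data frame with columns `symbol`, `index` and `meaning`.
#' @export
#' @examples
#' finding_vocabulary()
finding_vocabulary <- function() {
  data.frame(symbol = FINDING_SYMBOLS,
             index = seq_along(FINDING_SYMBOLS) - 1L,
             meaning = FINDING_MEANINGS,
             stringsAsFactors = FALSE)
}

#' Plan vocabulary
#'
#' The four per-tooth prosthesis choices with their fixed 0-based indices:
#' `-` (no prosthesis), `K` (crown), `B` (bridge unit), `E` (replacement by
#' removable denture).
#'
#' @return A data frame with columns `symbol`, `index` and `meaning`.
#' @export
plan_vocabulary <- function() {
  data.frame(symbol = PLAN_SYMBOLS,
             index = seq_along(PLAN_SYMBOLS) - 1L,
             meaning = PLAN_MEANINGS,
             stringsAsFactors = FALSE)
}

#' Tooth positions of the modelled jaw
#'
#' One jaw is modelled as 16 ordered positions; positions 1 and 16 are the
#' wisdom teeth. FDI labels follow the upper-jaw sequence 18..11, 21..28 and
#' are cosmetic.
#'
#' @return A data frame with columns `position`, `fdi_label`, `is_wisdom`.
#' @export
tooth_positions <- function() {
  data.frame(position = seq_len(N_TEETH),
             fdi_label = FDI_LABELS,
             is_wisdom = seq_len(N_TEETH) %in% WISDOM_POSITIONS,
             stringsAsFactors = FALSE)
}

#' Parse a 16-token chart
#'
#' Accepts either a single whitespace/comma separated string or a character
#' vector of 16 tokens and validates it against the finding or plan
#' vocabulary.
#'
#' @param tokens Character scalar (tokens separated by spaces or commas) or
#'   character vector of length 16.
#' @param vocabulary `"finding"` or `"plan"`.
#' @return A character vector of length 16 of class `findings_chart` or
#'   `plan_chart`.
#' @export
#' @examples
#' parse_chart("f . . k b k . . . . . . . . . .", "finding")
parse_chart <- function(tokens, vocabulary = c("finding", "plan")) {
  vocabulary <- match.arg(vocabulary)
  tokens <- as.character(tokens)
  if (length(tokens) == 1L && grepl("[,[:space:]]", tokens))
    tokens <- strsplit(trimws(tokens), "[,[:space:]]+")[[1L]]
  if (length(tokens) != N_TEETH)
    stop(sprintf("a chart needs %d tokens, got %d", N_TEETH, length(tokens)),
         call. = FALSE)
  vocab <- if (vocabulary == "finding") FINDING_SYMBOLS else PLAN_SYMBOLS
  bad <- which(!(tokens %in% vocab))
  if (length(bad))
    stop(sprintf("unknown %s symbol '%s' at position %d",
                 vocabulary, tokens[bad[1L]], bad[1L]), call. = FALSE)
  cls <- if (vocabulary == "finding") "findings_chart" else "plan_chart"
  structure(tokens, class = c(cls, "dental_chart"))
}

#' Format a chart as its text form
#'
#' @param chart A findings or plan chart (character vector of 16 tokens).
#' @return A single string with the 16 tokens separated by single spaces.
#' @export
format_chart <- function(chart) paste(as.character(chart), collapse = " ")

#' @export
print.dental_chart <- function(x, ...) {
  kind <- if (inherits(x, "findings_chart")) "findings" else "plan"
  cat(sprintf("<%s chart>\n", kind))
  cat(" FDI: ", paste(sprintf("%3s", FDI_LABELS), collapse = ""), "\n", sep = "")
  cat("     ", paste(sprintf("%3s", as.character(x)), collapse = ""), "\n", sep = "")
  invisible(x)
}

# Internal normalizers: accept classed charts, plain 16-vectors or a single
# string, always return a validated plain character vector.
as_findings <- function(x) {
  x <- unclass(x)
  attributes(x) <- NULL
  unclass(parse_chart(x, "finding"))
}

as_plan <- function(x) {
  x <- unclass(x)
  attributes(x) <- NULL
  unclass(parse_chart(x, "plan"))
}

#' Encode a findings chart as integer indices
#'
#' Maps each of the 16 finding tokens to its fixed 0-based index from
#' [finding_vocabulary()]. The encoding is invertible via
#' [decode_findings()].
#'
#' @param chart A findings chart.
#' @return Integer vector of length 16 with values in 0..9.
#' @export
encode_findings <- function(chart) {
  match(as_findings(chart), FINDING_SYMBOLS) - 1L
}

#' Decode integer indices back to a findings chart
#'
#' @param indices Integer vector of length 16 with values in 0..9.
#' @return A `findings_chart`.
#' @export
decode_findings <- function(indices) {
  indices <- as.integer(indices)
  if (length(indices) != N_TEETH || anyNA(indices) ||
      any(indices < 0L | indices >= length(FINDING_SYMBOLS)))
    stop("indices must be 16 integers in 0..9", call. = FALSE)
  structure(FINDING_SYMBOLS[indices + 1L],
            class = c("findings_chart", "dental_chart"))
}

#' One-hot encode a plan chart
#'
#' @param chart A plan chart.
#' @return A 16 x 4 binary matrix; row i has a single 1 at the fixed index
#'   of the plan code at position i.
#' @export
encode_plan <- function(chart) {
  chart <- as_plan(chart)
  m <- matrix(0L, nrow = N_TEETH, ncol = length(PLAN_SYMBOLS),
              dimnames = list(NULL, PLAN_SYMBOLS))
  m[cbind(seq_len(N_TEETH), match(chart, PLAN_SYMBOLS))] <- 1L
  m
}

#' Decode per-tooth class probabilities into a plan chart
#'
#' Takes the row-stochastic 16 x 4 output of a model and picks the most
#' probable plan code per tooth; ties break toward the lowest index.
#'
#' @param probabilities Numeric 16 x 4 matrix; every row must sum to 1
#'   within `tolerance`.
#' @param tolerance Allowed deviation of each row sum from 1.
#' @return A `plan_chart`.
#' @export
decode_plan <- function(probabilities, tolerance = 1e-6) {
  probabilities <- as.matrix(probabilities)
  if (!is.numeric(probabilities) ||
      nrow(probabilities) != N_TEETH ||
      ncol(probabilities) != length(PLAN_SYMBOLS))
    stop("probabilities must be a numeric 16 x 4 matrix", call. = FALSE)
  if (any(probabilities < 0))
    stop("probabilities must be nonnegative", call. = FALSE)
  rs <- rowSums(probabilities)
  off <- which(abs(rs - 1) > tolerance)
  if (length(off))
    stop(sprintf("row %d sums to %.8f, not 1", off[1L], rs[off[1L]]),
         call. = FALSE)
  idx <- max.col(probabilities, ties.method = "first")
  structure(PLAN_SYMBOLS[idx], class = c("plan_chart", "dental_chart"))
}
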