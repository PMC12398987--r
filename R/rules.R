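# Deterministic standard-care planner for one jaw. This is both the
# labelling function for synthetic cases and the oracle that trained
# networks are scored against.
#
# Structural rules on findings charts:
#   R1  every maximal run of pontics (b/bw) is flanked by crowns (k/kw) on
#       both sides -- no cantilever bridges exist in the findings
#   R2  within one FDP (a maximal k/kw/b/bw block containing a pontic)
#       sufficiency is uniform: all {k,b} or all {kw,bw}
#   R3  RDP-replaced teeth are uniformly sufficient (e) or uniformly
#       insufficient (ew) across the chart

# Teeth that can anchor a new bridge: natural teeth (sufficient or
# preservation-worthy) and crowns. Pontics, RDP teeth and gaps cannot.
CROWNABLE <- c(".", "ww", "k", "kw")

empty_violations <- function() {
  data.frame(rule_id = character(), position = integer(),
             message = character(), stringsAsFactors = FALSE)
}

#' Validate the structure of a findings chart
#'
#' Checks the three structural rules every generated chart must satisfy:
#' pontic runs flanked by crowns on both sides (R1), uniform sufficiency
#' within each fixed dental prosthesis (R2), and all-or-none insufficiency
#' of RDP-replaced teeth (R3).
#'
#' @param chart A findings chart.
#' @return A data frame of violations with columns `rule_id`, `position`
#'   and `message`; zero rows when the chart is structurally valid.
#' @export
#' @examples
#' validate_findings(rep(".", 16))                       # no violations
#' validate_findings(c(".", ".", ".", ".", "b", rep(".", 11)))  # R1
validate_findings <- function(chart) {
  chart <- as_findings(chart)
  viol <- list()
  add <- function(rule, pos, msg)
    viol[[length(viol) + 1L]] <<- data.frame(rule_id = rule, position = pos,
                                             message = msg,
                                             stringsAsFactors = FALSE)

  is_fdp <- chart %in% c("k", "kw", "b", "bw")
  r <- rle(is_fdp)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in seq_along(r$values)) {
    if (!r$values[j]) next
    s <- starts[j]; e <- ends[j]
    block <- chart[s:e]
    if (!any(block %in% c("b", "bw"))) next    # crowns only, no FDP span
    pr <- rle(block %in% c("b", "bw"))
    pe <- cumsum(pr$lengths)
    ps <- pe - pr$lengths + 1L
    for (q in seq_along(pr$values)) {
      if (!pr$values[q]) next
      ls <- s + ps[q] - 1L
      le <- s + pe[q] - 1L
      left_ok <- ls > 1L && chart[ls - 1L] %in% c("k", "kw")
      right_ok <- le < N_TEETH && chart[le + 1L] %in% c("k", "kw")
      if (!left_ok || !right_ok)
        add("R1", ls, sprintf(
          "pontic run at positions %d-%d is not flanked by crowns on both sides",
          ls, le))
    }
    suff <- block %in% c("k", "b")
    if (any(suff) && any(!suff))
      add("R2", s, sprintf(
        "mixed sufficiency within the FDP spanning positions %d-%d", s, e))
  }
  if (any(chart == "e") && any(chart == "ew"))
    add("R3", which(chart == "ew")[1L],
        "RDP-replaced teeth mix sufficient (e) and insufficient (ew) entries")
  if (length(viol)) do.call(rbind, viol) else empty_violations()
}

#' Find gap segments in a findings chart
#'
#' A gap is a maximal run of positions whose tooth is missing (`f`) or
#' condemned (`x`). Each segment is annotated with whether a crownable
#' tooth (one of `.`, `ww`, `k`, `kw`) exists on either side and whether
#' the whole run lies at wisdom positions.
#'
#' @param chart A findings chart.
#' @return A data frame with columns `start`, `end`, `bounded_left`,
#'   `bounded_right`, `wisdom_only`; zero rows when no tooth is missing.
#' @export
find_gaps <- function(chart) {
  chart <- as_findings(chart)
  miss <- chart %in% c("f", "x")
  if (!any(miss))
    return(data.frame(start = integer(), end = integer(),
                      bounded_left = logical(), bounded_right = logical(),
                      wisdom_only = logical()))
  r <- rle(miss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  out <- data.frame(start = starts[keep], end = ends[keep])
  out$bounded_left <- out$start > 1L &
    chart[pmax(out$start - 1L, 1L)] %in% CROWNABLE
  out$bounded_right <- out$end < N_TEETH &
    chart[pmin(out$end + 1L, N_TEETH)] %in% CROWNABLE
  out$wisdom_only <- mapply(function(s, e) all(s:e %in% WISDOM_POSITIONS),
                            out$start, out$end)
  out
}

# Gap segments after trimming wisdom positions off the jaw ends: a missing
# wisdom tooth never requires replacement, so it takes no part in the
# boundedness or threshold logic. Boundedness is re-derived on the trimmed
# spans (the neighbour of a trimmed span can be a missing wisdom tooth,
# which cannot anchor a bridge).
effective_gaps <- function(chart) {
  g <- find_gaps(chart)
  if (!nrow(g)) return(g)
  g$start[g$start == 1L] <- 2L
  g$end[g$end == N_TEETH] <- N_TEETH - 1L
  g <- g[g$start <= g$end, , drop = FALSE]
  if (nrow(g)) {
    g$bounded_left <- chart[g$start - 1L] %in% CROWNABLE
    g$bounded_right <- chart[g$end + 1L] %in% CROWNABLE
    g$wisdom_only <- FALSE
  }
  g
}

#' Count teeth that require replacement
#'
#' Number of non-wisdom positions holding a missing (`f`) or condemned
#' (`x`) tooth. Missing wisdom teeth never require replacement.
#'
#' @param chart A findings chart.
#' @return Integer count.
#' @export
count_replacement_needs <- function(chart) {
  chart <- as_findings(chart)
  inner <- setdiff(seq_len(N_TEETH), WISDOM_POSITIONS)
  sum(chart[inner] %in% c("f", "x"))
}

#' Does a findings chart require a removable denture?
#'
#' The RDP pathway fires when (a) four or more non-wisdom teeth require
#' replacement, (b) any gap (after trimming wisdom ends) lacks a crownable
#' abutment on either side -- cantilever bridges are not permitted -- or
#' (c) an existing RDP is insufficient (`ew` present), which forces renewal
#' and routes any new replacements into the denture.
#'
#' @param chart A findings chart.
#' @return Logical scalar with attribute `reasons`, a character vector
#'   among `"four_or_more"`, `"unbounded_gap"`, `"rdp_renewal"`.
#' @export
requires_rdp <- function(chart) {
  chart <- as_findings(chart)
  reasons <- character()
  if (count_replacement_needs(chart) >= 4L)
    reasons <- c(reasons, "four_or_more")
  g <- effective_gaps(chart)
  if (nrow(g) && any(!g$bounded_left | !g$bounded_right))
    reasons <- c(reasons, "unbounded_gap")
  if (any(chart == "ew"))
    reasons <- c(reasons, "rdp_renewal")
  structure(length(reasons) > 0L, reasons = reasons)
}

#' Plan the standard-care prosthesis for a findings chart
#'
#' Deterministically maps a structurally valid findings chart to a plan
#' chart over `-`, `K`, `B`, `E`:
#'
#' * missing wisdom teeth are left untreated (`-`);
#' * when [requires_rdp()] fires, every non-wisdom missing/condemned tooth
#'   and every RDP tooth goes into one removable denture (`E`) -- an
#'   existing denture is renewed along with any extension;
#' * otherwise each gap is bridged: gap positions become pontics (`B`) and
#'   the flanking teeth become abutment crowns (`K`);
#' * insufficient fixed work is renewed in place (`kw` to `K`, `bw` to
#'   `B`), and preservation-worthy insufficient natural teeth are crowned
#'   (`ww` to `K`);
#' * everything else needs no prosthesis (`-`).
#'
#' @param chart A findings chart; must pass [validate_findings()].
#' @param check Validate the chart first (default `TRUE`). Internal callers
#'   that have already validated can skip the re-check.
#' @param explain Attach a per-position rule trace as attribute `rules`.
#' @return A `plan_chart`.
#' @export
#' @examples
#' plan_case(parse_chart(". . . . . . . f . . . . . . . ."))
plan_case <- function(chart, check = TRUE, explain = FALSE) {
  chart <- as_findings(chart)
  if (check) {
    v <- validate_findings(chart)
    if (nrow(v))
      stop(paste0("invalid findings chart:\n",
                  paste0("  [", v$rule_id, "] ", v$message, collapse = "\n")),
           call. = FALSE)
  }
  plan <- rep("-", N_TEETH)
  rules <- rep("P6", N_TEETH)
  rdp <- requires_rdp(chart)

  missing_pos <- which(chart %in% c("f", "x"))
  rules[intersect(missing_pos, WISDOM_POSITIONS)] <- "P1"

  if (rdp) {
    tgt <- setdiff(missing_pos, WISDOM_POSITIONS)
    plan[tgt] <- "E"; rules[tgt] <- "P2"
    plan[chart == "ew"] <- "E"; rules[chart == "ew"] <- "P2"
    plan[chart == "e"] <- "E"; rules[chart == "e"] <- "P2"
  } else {
    g <- effective_gaps(chart)
    for (i in seq_len(nrow(g))) {
      span <- g$start[i]:g$end[i]
      plan[span] <- "B"; rules[span] <- "P3"
      ab <- c(g$start[i] - 1L, g$end[i] + 1L)
      plan[ab] <- "K"; rules[ab] <- "P3"
    }
  }
  plan[chart == "kw"] <- "K"; rules[chart == "kw"] <- "P4"
  plan[chart == "bw"] <- "B"; rules[chart == "bw"] <- "P4"
  plan[chart == "ww"] <- "K"; rules[chart == "ww"] <- "P5"

  out <- structure(plan, class = c("plan_chart", "dental_chart"))
  if (explain) attr(out, "rules") <- rules
  out
}

#' Does a plan include a fixed bridge?
#'
#' @param plan A plan chart.
#' @return `TRUE` iff any position holds a bridge unit (`B`).
#' @export
plan_contains_fdp <- function(plan) {
  any(as_plan(plan) == "B")
}
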