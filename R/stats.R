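# Nonparametric group comparison: Kruskal-Wallis omnibus (via
# stats::kruskal.test) followed by pairwise Dunn tests on the pooled mean
# ranks with tie correction, Bonferroni-corrected two-sided p values, and
# the z-based effect size r = |z| / sqrt(n1 + n2) per pair. The Dunn test
# is implemented here because no installed package provides it.

check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("groups must be a list of at least two numeric vectors",
         call. = FALSE)
  if (any(lengths(groups) == 0L))
    stop("every group must be non-empty", call. = FALSE)
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("group", seq_along(groups))
  lapply(groups, as.numeric)
}

#' Kruskal-Wallis omnibus test
#'
#' Rank-based H with tie correction and a chi-square approximation with
#' k - 1 degrees of freedom. When all values across all groups are
#' identical the test is degenerate and `H = 0`, `p = 1` is returned.
#'
#' @param groups Named list of numeric vectors.
#' @return A list with `h_statistic`, `p_value`, `df`.
#' @export
#' @examples
#' kruskal_wallis(list(a = c(1, 2, 3), b = c(10, 11, 12)))
kruskal_wallis <- function(groups) {
  groups <- check_groups(groups)
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)))
  if (length(unique(x)) == 1L)
    return(list(h_statistic = 0, p_value = 1, df = nlevels(g) - 1L))
  kt <- stats::kruskal.test(x, g)
  list(h_statistic = unname(kt$statistic), p_value = unname(kt$p.value),
       df = unname(kt$parameter))
}

#' Dunn post-hoc test with Bonferroni correction
#'
#' Pairwise z statistics from the pooled mean ranks with tie correction,
#' two-sided p values multiplied by the number of pairs k(k-1)/2 (capped
#' at 1), and the effect size r = |z| / sqrt(n1 + n2) per pair.
#'
#' @param groups Named list of numeric vectors.
#' @return A data frame with one row per pair: `group1`, `group2`, `z`,
#'   `p_value`, `p_bonferroni`, `effect_size_r`.
#' @export
dunn_bonferroni <- function(groups) {
  groups <- check_groups(groups)
  k <- length(groups)
  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), lengths(groups))
  N <- length(x)
  rk <- rank(x)
  mean_ranks <- tapply(rk, g, mean)[names(groups)]
  n <- lengths(groups)

  tie_sizes <- table(x)
  tie_term <- sum(tie_sizes^3 - tie_sizes) / (12 * (N - 1))
  var_base <- N * (N + 1) / 12 - tie_term

  pairs <- utils::combn(names(groups), 2L)
  n_pairs <- ncol(pairs)
  rows <- lapply(seq_len(n_pairs), function(j) {
    g1 <- pairs[1L, j]; g2 <- pairs[2L, j]
    se2 <- var_base * (1 / n[[g1]] + 1 / n[[g2]])
    z <- if (se2 <= 0) 0 else
      (mean_ranks[[g1]] - mean_ranks[[g2]]) / sqrt(se2)
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(group1 = g1, group2 = g2, z = z, p_value = p,
               p_bonferroni = min(1, p * n_pairs),
               effect_size_r = abs(z) / sqrt(n[[g1]] + n[[g2]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Full group comparison: omnibus plus post-hoc
#'
#' @param groups Named list of numeric accuracy samples, or a
#'   `run_results` data frame (grouped by architecture).
#' @return An object of class `group_comparison` with `groups`,
#'   `h_statistic`, `omnibus_p`, `df` and the `pairwise` data frame from
#'   [dunn_bonferroni()].
#' @export
compare_groups <- function(groups) {
  if (is.data.frame(groups))
    groups <- split(groups$exact_set_accuracy, groups$arch)
  groups <- check_groups(groups)
  kw <- kruskal_wallis(groups)
  structure(list(groups = groups, h_statistic = kw$h_statistic,
                 omnibus_p = kw$p_value, df = kw$df,
                 pairwise = dunn_bonferroni(groups)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4f, df = %d, p = %.4g\n",
              x$h_statistic, x$df, x$omnibus_p))
  cat(sprintf("Dunn-Bonferroni pairwise comparisons (%d pairs):\n",
              nrow(x$pairwise)))
  pw <- x$pairwise
  pw$z <- round(pw$z, 3)
  pw$p_value <- signif(pw$p_value, 3)
  pw$p_bonferroni <- signif(pw$p_bonferroni, 3)
  pw$effect_size_r <- round(pw$effect_size_r, 2)
  print(pw, row.names = FALSE)
  invisible(x)
}
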