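# Brute-force rank statistics, written independently of both the package
# implementation and stats::kruskal.test: mid-ranks from explicit
# comparison counts, tie sizes by enumeration.

oracle_ranks <- function(x) {
  vapply(x, function(v) sum(x < v) + (sum(x == v) + 1) / 2, numeric(1))
}

oracle_kw_h <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  rk <- oracle_ranks(x)
  rsums <- tapply(rk, g, sum)
  h <- 12 / (N * (N + 1)) * sum(rsums^2 / lengths(groups)) - 3 * (N + 1)
  ties <- table(x)
  correction <- 1 - sum(ties^3 - ties) / (N^3 - N)
  h / correction
}

oracle_dunn_z <- function(groups, i, j) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  rk <- oracle_ranks(x)
  mr <- tapply(rk, g, mean)
  ties <- table(x)
  sigma2 <- (N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))) *
    (1 / lengths(groups)[i] + 1 / lengths(groups)[j])
  unname((mr[[i]] - mr[[j]]) / sqrt(sigma2))
}
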