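# Internal helpers shared across modules.

#' @importFrom rlang .data abort warn
#' @importFrom tibble tibble as_tibble
NULL

# One-sided Mann-Whitney U: alternative "a stochastically greater than b".
# Normal approximation with tie correction and continuity correction;
# exact distribution (stats::pwilcox) when both samples are small and
# tie-free. Degenerate all-tied input yields p = 0.5.
mwu_greater <- function(a, b, exact_max = 30L) {
  n1 <- length(a)
  n2 <- length(b)
  r <- rank(c(a, b))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(c(a, b)) > 0L
  if (n1 < exact_max && n2 < exact_max && !has_ties) {
    p <- stats::pwilcox(u - 1, n1, n2, lower.tail = FALSE)
  } else {
    mu <- n1 * n2 / 2
    nt <- tabulate(match(r, unique(r)))
    tie_term <- sum(nt^3 - nt)
    s2 <- n1 * n2 / 12 * ((n1 + n2 + 1) - tie_term / ((n1 + n2) * (n1 + n2 - 1)))
    p <- if (s2 <= 0) 0.5 else stats::pnorm((u - mu - 0.5) / sqrt(s2), lower.tail = FALSE)
  }
  list(statistic = u, p_value = min(max(p, 0), 1))
}

# Rank at which each gene first enters the union of the top-x prefixes of
# several rankings. `positions` is an N x m integer matrix; row = gene in the
# canonical gene order, column = ranking.
entry_ranks <- function(positions) {
  out <- positions[, 1L]
  m <- ncol(positions)
  if (m > 1L) for (j in 2:m) out <- pmin(out, positions[, j])
  out
}

# Cumulative number of entries <= x for x = 1..N, given entry ranks.
cum_entries <- function(entries, N) {
  cumsum(tabulate(entries, nbins = N))
}

# Equally spaced knot grid over 1..N (always including N, deduplicated).
knot_grid <- function(N, n_knots) {
  if (n_knots >= N) return(seq_len(N))
  sort(unique(c(round(seq_len(n_knots) * N / n_knots), N)))
}

run_seeded <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
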