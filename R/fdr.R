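#' Permutation false discovery rate for univariate enrichment calls
#'
#' Calibrates the Mann-Whitney p-value threshold for one platform by
#' comparing how many gene sets pass each threshold on the real scores
#' against how many pass on score-shuffled data. Each trial permutes the
#' gene-to-score assignment once (gene set memberships stay fixed, one
#' shared permutation per trial across all sets) and recomputes every gene
#' set's univariate walk-versus-null p-value. The FDR at a threshold is
#'
#' `min(total permuted significant / (empirical significant * n_trials), 1)`
#'
#' and is reported as 1 when no empirical set passes (the ratio is
#' undefined there; 1 is the conservative convention).
#'
#' @param score_table Tibble with a `gene` column and platform score
#'   columns.
#' @param feature Platform column to calibrate.
#' @param gene_sets Collection tibble or named list of member vectors.
#' @param universe Universe genes (default: all genes in the table).
#' @param thresholds Decreasing grid of p-value thresholds
#'   (default `10^-(1:10)`).
#' @param n_trials Number of permutation trials (default 1000, as used for
#'   full-scale calibration; scale down for quick runs).
#' @param n_knots Knot count for the walks (default 500).
#' @param min_size Minimum post-intersection set size (default 1).
#' @param seed Optional integer seed; fixing it reproduces the curve
#'   exactly.
#' @return An `fdr_curve` tibble: `threshold`, `n_significant` (empirical
#'   count), `mean_permuted` (mean permuted count per trial), `fdr`; with
#'   attributes `feature`, `n_trials`, `seed`.
#' @export
permutation_fdr <- function(score_table, feature, gene_sets, universe = NULL,
                            thresholds = 10^-(1:10), n_trials = 1000L,
                            n_knots = 500L, min_size = 1L, seed = NULL) {
  if (n_trials < 1L) abort("n_trials must be >= 1")
  universe <- universe %||% score_table$gene
  collection <- restrict_gene_sets(as_gene_sets(gene_sets), universe, min_size = min_size)
  if (nrow(collection) == 0L) abort("no gene set survives the universe intersection and size filter")
  thresholds <- sort(thresholds, decreasing = TRUE)
  ranked <- rank_genes(score_table, feature, universe = universe)
  N <- nrow(ranked)
  knots <- knot_grid(N, n_knots)
  null_vals <- knots / N

  # membership indicators in ranked order; per-set p for one gene order
  hits <- lapply(collection$members, function(m) ranked$gene %in% m)
  set_pvals <- function(ord) {
    vapply(hits, function(h) {
      hv <- h[ord]
      K <- sum(hv)
      mwu_greater(cumsum(hv)[knots] / K, null_vals)$p_value
    }, numeric(1L))
  }
  emp_p <- set_pvals(seq_len(N))
  perm_counts <- run_seeded(seed, {
    vapply(seq_len(n_trials), function(b) {
      p <- set_pvals(sample.int(N))
      vapply(thresholds, function(th) sum(p <= th), numeric(1L))
    }, numeric(length(thresholds)))
  })
  perm_counts <- matrix(perm_counts, nrow = length(thresholds))
  emp_counts <- vapply(thresholds, function(th) sum(emp_p <= th), numeric(1L))
  total_perm <- rowSums(perm_counts)
  fdr <- ifelse(emp_counts == 0, 1, pmin(total_perm / (emp_counts * n_trials), 1))
  out <- tibble(
    threshold = thresholds,
    n_significant = as.integer(emp_counts),
    mean_permuted = total_perm / n_trials,
    fdr = fdr
  )
  structure(out,
    feature = feature, n_trials = n_trials, seed = seed,
    class = c("fdr_curve", class(out))
  )
}
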