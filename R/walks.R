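#' Rank genes of one platform into a ranked list
#'
#' Sorts universe genes by descending score. Ties are broken by ascending
#' gene identifier so rankings are deterministic and seed-free; genes with a
#' missing score (or absent from the table) are appended after all scored
#' genes, in identifier order, which keeps a common list length N across
#' platforms as joint walks require.
#'
#' @param score_table Tibble with a `gene` column and one numeric column per
#'   platform.
#' @param feature Name of the platform column to rank by.
#' @param universe Optional character vector restricting (and defining) the
#'   gene universe; default all genes in the table.
#' @return A `ranked_list`: tibble with columns `rank`, `gene`, `score` and
#'   attribute `feature`.
#' @export
rank_genes <- function(score_table, feature, universe = NULL) {
  stopifnot(is.data.frame(score_table), "gene" %in% names(score_table))
  if (!feature %in% names(score_table)) {
    abort(paste0("unknown feature '", feature, "'"))
  }
  genes <- universe %||% score_table$gene
  if (anyDuplicated(genes) > 0L) abort("universe contains duplicate gene identifiers")
  s <- score_table[[feature]][match(genes, score_table$gene)]
  # radix keys make identifier tie-breaks locale-independent
  key <- match(genes, sort(genes, method = "radix"))
  ord <- order(is.na(s), -ifelse(is.na(s), 0, s), key)
  out <- tibble(rank = seq_along(genes), gene = genes[ord], score = s[ord])
  structure(out, feature = feature, class = c("ranked_list", class(out)))
}

# Walk-curve container: a rank/value tibble carrying the universe size N,
# gene-set size K, curve kind and the features involved.
new_walk_curve <- function(ranks, values, N, K, kind, features,
                           normalized = FALSE, permuted = NA_character_,
                           se = NULL) {
  out <- tibble(rank = as.integer(ranks), value = values)
  if (!is.null(se)) out$se <- se
  structure(
    out,
    N = as.integer(N), K = as.integer(K), kind = kind,
    features = features, normalized = normalized, permuted = permuted,
    class = c("walk_curve", class(out))
  )
}

#' @export
print.walk_curve <- function(x, ...) {
  cat(sprintf(
    "<walk_curve> kind=%s features=%s N=%d K=%d %s, %d ranks\n",
    attr(x, "kind"), paste(attr(x, "features"), collapse = "+"),
    attr(x, "N"), attr(x, "K"),
    if (attr(x, "normalized")) "normalized" else "raw",
    nrow(x)
  ))
  NextMethod()
}

walk_attrs <- function(curve) {
  attributes(curve)[c("N", "K", "kind", "features", "normalized", "permuted")]
}

check_same_universe <- function(ranked_lists) {
  genes <- sort(ranked_lists[[1L]]$gene, method = "radix")
  for (rl in ranked_lists[-1L]) {
    if (!identical(sort(rl$gene, method = "radix"), genes)) {
      abort("ranked lists are defined over different universes")
    }
  }
  invisible(genes)
}

# N x m matrix of each gene's rank in each list, rows in canonical
# (sorted-identifier) gene order.
position_matrix <- function(ranked_lists) {
  genes <- check_same_universe(ranked_lists)
  vapply(ranked_lists, function(rl) match(genes, rl$gene), integer(length(genes)))
}

members_in_universe <- function(members, genes) {
  hit <- genes %in% members
  if (!any(hit)) abort("gene set has no members in the universe (K = 0)")
  hit
}

#' Enrichment random walk of one ranked list
#'
#' The walk `y(x)` counts, at each rank x, how many of the top-x genes belong
#' to the gene set: it starts at 0 and increments by one whenever the gene at
#' rank x is a member. Only members inside the universe count, so K is the
#' post-intersection set size.
#'
#' @param ranked A `ranked_list` from [rank_genes()].
#' @param members Character vector of gene set members.
#' @return A raw (hit-count) `walk_curve` of kind `"empirical"` over ranks
#'   1..N.
#' @export
univariate_walk <- function(ranked, members) {
  hits <- ranked$gene %in% members
  K <- sum(hits)
  if (K == 0L) abort("gene set has no members in the universe (K = 0)")
  new_walk_curve(
    ranks = seq_len(nrow(ranked)), values = cumsum(hits),
    N = nrow(ranked), K = K, kind = "empirical",
    features = attr(ranked, "feature") %||% "feature"
  )
}

#' Straight-line null walk
#'
#' Under the null hypothesis that the ranking is uninformative, gene set
#' members fall uniformly along the list and the expected walk is the
#' straight line `(K / N) * x`.
#'
#' @param N Universe size.
#' @param K Gene set size (1 <= K <= N).
#' @param ranks Integer rank grid (default 1..N).
#' @return A raw `walk_curve` of kind `"null"` (real-valued).
#' @export
null_walk <- function(N, K, ranks = seq_len(N)) {
  if (K < 1L || K > N) abort("need 1 <= K <= N")
  if (any(ranks < 0L | ranks > N)) abort("ranks must lie in 0..N")
  new_walk_curve(ranks, (K / N) * ranks, N = N, K = K, kind = "null", features = "null")
}

#' Joint enrichment walk over several ranked lists
#'
#' At rank x, the joint walk counts the gene set members in the union of the
#' top-x prefixes of every list. It therefore lies on or above each
#' single-list walk at every rank.
#'
#' @param ranked_lists List of two or more `ranked_list` objects over the
#'   same universe.
#' @param members Character vector of gene set members.
#' @return A raw `walk_curve` of kind `"joint"` over ranks 1..N.
#' @export
joint_walk <- function(ranked_lists, members) {
  if (length(ranked_lists) < 2L) abort("joint_walk needs at least 2 ranked lists")
  pos <- position_matrix(ranked_lists)
  genes <- sort(ranked_lists[[1L]]$gene, method = "radix")
  hit <- members_in_universe(members, genes)
  N <- length(genes)
  entries <- entry_ranks(pos)
  new_walk_curve(
    ranks = seq_len(N), values = cum_entries(entries[hit], N),
    N = N, K = sum(hit), kind = "joint",
    features = vapply(ranked_lists, function(rl) attr(rl, "feature") %||% "feature", character(1L))
  )
}

#' Expected joint walk of fully randomised rankings
#'
#' The union of m independent uniformly random top-x prefixes covers a gene
#' with probability `1 - ((N - x) / N)^m`, so the expected joint hit count is
#' `K * (1 - ((N - x) / N)^m)`. This exceeds the straight-line null for
#' m >= 2 and serves as the bias-corrected baseline for joint-versus-null
#' comparisons (off by default in [mgsea()]).
#'
#' @param N Universe size.
#' @param K Gene set size.
#' @param m Number of platforms in the union.
#' @param ranks Integer rank grid (default 1..N).
#' @return A raw `walk_curve` of kind `"null"`.
#' @export
null_joint_walk <- function(N, K, m, ranks = seq_len(N)) {
  if (K < 1L || K > N) abort("need 1 <= K <= N")
  if (m < 1L) abort("m must be >= 1")
  new_walk_curve(
    ranks, K * (1 - ((N - ranks) / N)^m),
    N = N, K = K, kind = "null", features = "null"
  )
}

#' Down-sample a walk to an equally spaced knot grid
#'
#' Keeps the curve values at `round(i * N / n_knots)` for i = 1..n_knots
#' (deduplicated, always including N). Consumers interpolate linearly
#' between knots, i.e. the down-sampled walk is a piecewise linear
#' approximation of the full curve.
#'
#' @param curve A `walk_curve` on the full 1..N grid (or any superset of the
#'   knots).
#' @param n_knots Number of knots (>= 2). Values above N are clamped to full
#'   resolution.
#' @return A `walk_curve` on the knot grid.
#' @export
downsample_knots <- function(curve, n_knots) {
  if (n_knots < 2L) abort("n_knots must be >= 2")
  N <- attr(curve, "N")
  knots <- knot_grid(N, n_knots)
  idx <- match(knots, curve$rank)
  if (anyNA(idx)) abort("curve does not cover the requested knot ranks")
  a <- walk_attrs(curve)
  new_walk_curve(
    knots, curve$value[idx],
    N = a$N, K = a$K, kind = a$kind, features = a$features,
    normalized = a$normalized, permuted = a$permuted
  )
}

#' Normalize a walk to the unit interval
#'
#' Divides hit counts by the gene set size K so curves of different sets are
#' comparable and can be read as cumulative distribution functions over
#' ranks. Idempotent.
#'
#' @param curve A `walk_curve`.
#' @return The normalized curve.
#' @export
normalize_walk <- function(curve) {
  if (isTRUE(attr(curve, "normalized"))) return(curve)
  a <- walk_attrs(curve)
  if (a$K < 1L) abort("cannot normalize a curve with K = 0")
  new_walk_curve(
    curve$rank, curve$value / a$K,
    N = a$N, K = a$K, kind = a$kind, features = a$features,
    normalized = TRUE, permuted = a$permuted,
    se = if ("se" %in% names(curve)) curve$se / a$K else NULL
  )
}

#' Export a walk curve as a rank/value TSV
#'
#' @param curve A `walk_curve`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_walk_tsv <- function(curve, path) {
  readr::write_tsv(as_tibble(curve), path, progress = FALSE)
  invisible(path)
}
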