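#' Multivariate gene set enrichment analysis
#'
#' Runs the full analysis for every gene set in a collection: builds the
#' empirical walk of each platform subset, the straight-line null, and the
#' analytic conditional walks; performs all pairwise one-sided Mann-Whitney
#' comparisons (16 for three platforms, see [enumerate_comparisons()]); and
#' classifies each gene set's combinatorial pattern of dominant and
#' redundant platforms (see [classify_pattern()]).
#'
#' @param score_table Tibble with a `gene` column and one numeric score
#'   column per platform (higher score = more informative).
#' @param gene_sets Collection tibble from [read_gmt()] or a named list of
#'   member vectors.
#' @param features Platform columns to use (default: every non-`gene`
#'   column; at least 2 — for a single platform compare
#'   [univariate_walk()] against [null_walk()] directly).
#' @param universe Character vector of universe genes (default: all genes
#'   in the score table). Gene sets are intersected with it and sets
#'   smaller than `min_size` afterwards are dropped.
#' @param n_knots Number of equally spaced ranks at which walks are
#'   evaluated (default 500; clamped to N).
#' @param threshold Mann-Whitney p-value threshold for calling a
#'   comparison significant (default 1e-10).
#' @param min_size Minimum post-intersection gene set size (default 1).
#' @param corrected_null Use the expected randomised joint walk
#'   ([null_joint_walk()]) instead of the straight line as the baseline for
#'   joint-versus-null comparisons, correcting the upward bias of prefix
#'   unions. Default `FALSE` (the straight-line convention).
#' @return An object of class `mgsea_result`: a list with `comparisons`
#'   (long tibble of all comparisons for all sets), `patterns` (one row per
#'   set with the dominant platforms, redundant pairs and pattern label)
#'   and the configuration. Use [generics::tidy()] / [generics::glance()]
#'   to extract tibbles and `autoplot()` for a p-value overview.
#' @examples
#' sim <- simulate_mgsea(model = 1, n_genes = 300, seed = 1, center = TRUE)
#' fit <- mgsea(sim_score_table(sim), sim_gene_sets(sim), n_knots = 300, threshold = 1e-4)
#' fit$patterns
#' @export
mgsea <- function(score_table, gene_sets, features = NULL, universe = NULL,
                  n_knots = 500L, threshold = 1e-10, min_size = 1L,
                  corrected_null = FALSE) {
  stopifnot(is.data.frame(score_table), "gene" %in% names(score_table))
  features <- features %||% setdiff(names(score_table), "gene")
  if (length(features) < 2L) {
    abort(paste0(
      "mgsea needs at least 2 platform columns; for a single platform ",
      "compare univariate_walk() against null_walk() directly"
    ))
  }
  universe <- universe %||% score_table$gene
  collection <- restrict_gene_sets(as_gene_sets(gene_sets), universe, min_size = min_size)
  if (nrow(collection) == 0L) {
    abort("no gene set survives the universe intersection and size filter")
  }
  ranked <- lapply(features, function(f) rank_genes(score_table, f, universe = universe))
  names(ranked) <- features
  pos <- position_matrix(ranked)
  genes <- check_same_universe(ranked)
  N <- length(genes)
  knots <- knot_grid(N, n_knots)
  specs <- enumerate_comparisons(features)

  # entry ranks and covered-gene counts per platform subset (set-independent)
  keys <- vapply(specs$subset, subset_key, character(1L))
  subsets <- specs$subset[!duplicated(keys)]
  names(subsets) <- unique(keys)
  entries <- lapply(subsets, function(s) entry_ranks(pos[, match(s, features), drop = FALSE]))
  n_cov <- lapply(entries, function(e) cum_entries(e, N)[knots])

  one_set <- function(members, set_name) {
    hit <- genes %in% members
    K <- sum(hit)
    k_cov <- lapply(entries, function(e) cum_entries(e[hit], N)[knots])
    walk_of <- function(s) k_cov[[subset_key(s)]] / K
    null_of <- function(s) {
      if (corrected_null && length(s) > 1L) 1 - ((N - knots) / N)^length(s) else knots / N
    }
    cond_of <- function(s, perm) {
      fx <- setdiff(s, perm)
      kf <- k_cov[[subset_key(fx)]]
      (kf + knots * (K - kf) / N) / K
    }
    rows <- lapply(seq_len(nrow(specs)), function(i) {
      s <- specs$subset[[i]]
      a <- walk_of(s)
      b <- if (specs$kind[i] == "vs_null") null_of(s) else cond_of(s, specs$permuted[i])
      res <- mwu_greater(a, b)
      tibble(
        set = set_name, comparison = specs$comparison[i], kind = specs$kind[i],
        subset = list(s), permuted = specs$permuted[i],
        statistic = res$statistic, p_value = res$p_value,
        significant = res$p_value <= threshold
      )
    })
    dplyr::bind_rows(rows)
  }

  comparisons <- dplyr::bind_rows(
    purrr::map2(collection$members, collection$set, one_set)
  )
  patterns <- dplyr::bind_rows(lapply(collection$set, function(nm) {
    res <- comparisons[comparisons$set == nm, , drop = FALSE]
    cls <- classify_pattern(res, features, threshold = threshold)
    dplyr::bind_cols(tibble(set = nm, K = length(intersect(collection$members[[match(nm, collection$set)]], genes))), cls)
  }))

  structure(
    list(
      comparisons = comparisons,
      patterns = patterns,
      features = features,
      threshold = threshold,
      knots = knots,
      N = N,
      corrected_null = corrected_null
    ),
    class = "mgsea_result"
  )
}

#' @export
print.mgsea_result <- function(x, ...) {
  cat(sprintf(
    "<mgsea_result> %d gene set(s), %d platforms (%s), N = %d, %d knots, threshold %.3g\n",
    nrow(x$patterns), length(x$features), paste(x$features, collapse = ", "),
    x$N, length(x$knots), x$threshold
  ))
  print(x$patterns[, c("set", "K", "pattern")], ...)
  invisible(x)
}

#' Tidy an mgsea result into one row per comparison
#'
#' @param x An `mgsea_result`.
#' @param ... Unused.
#' @return The long comparison tibble (`set`, `comparison`, `kind`,
#'   `permuted`, `statistic`, `p_value`, `significant`).
#' @export
tidy.mgsea_result <- function(x, ...) {
  dplyr::select(x$comparisons, !"subset")
}

#' One-row summary of an mgsea result
#'
#' @param x An `mgsea_result`.
#' @param ... Unused.
#' @return Tibble with the run configuration and pattern counts.
#' @export
glance.mgsea_result <- function(x, ...) {
  tibble(
    n_sets = nrow(x$patterns),
    n_features = length(x$features),
    n_comparisons = nrow(x$comparisons),
    n_knots = length(x$knots),
    N = x$N,
    threshold = x$threshold,
    n_with_dominant = sum(x$patterns$pattern != "none"),
    n_with_redundancy = sum(vapply(x$patterns$redundant, nrow, integer(1L)) > 0L)
  )
}

#' All walk curves of one gene set, ready for plotting
#'
#' Builds the normalized empirical walk of every platform subset, the null
#' line and every single-platform conditional walk on a shared knot grid —
#' the full picture behind one gene set's 16 comparisons.
#'
#' @inheritParams mgsea
#' @param members Character vector of gene set members.
#' @return An `mgsea_curves` tibble: `curve` (label), `kind`, `rank`,
#'   `value`.
#' @export
walk_curves <- function(score_table, members, features = NULL, universe = NULL,
                        n_knots = 500L) {
  features <- features %||% setdiff(names(score_table), "gene")
  if (is.data.frame(members)) members <- members$members[[1L]]
  universe <- universe %||% score_table$gene
  ranked <- lapply(features, function(f) rank_genes(score_table, f, universe = universe))
  names(ranked) <- features
  N <- length(universe)
  knots <- knot_grid(N, n_knots)
  specs <- enumerate_comparisons(features)
  keys <- vapply(specs$subset, subset_key, character(1L))
  subsets <- specs$subset[!duplicated(keys)]
  curves <- list()
  add <- function(label, kind, value) {
    curves[[length(curves) + 1L]] <<- tibble(curve = label, kind = kind, rank = knots, value = value)
  }
  K <- NULL
  for (s in subsets) {
    w <- if (length(s) == 1L) {
      univariate_walk(ranked[[s]], members)
    } else {
      joint_walk(ranked[s], members)
    }
    K <- attr(w, "K")
    w <- normalize_walk(downsample_knots(w, length(knots)))
    add(paste0("C(", paste(s, collapse = ","), ")"), attr(w, "kind"), w$value)
  }
  add("null", "null", knots / N)
  for (i in which(specs$kind == "vs_conditional")) {
    s <- specs$subset[[i]]
    perm <- specs$permuted[i]
    cond <- expected_conditional_walk(ranked[setdiff(s, perm)], members,
      knots = knots, permuted = perm
    )
    add(curve_label(cond), "conditional_expected", cond$value / attr(cond, "K"))
  }
  out <- dplyr::bind_rows(curves)
  structure(out, N = N, K = K, class = c("mgsea_curves", class(out)))
}

#' Write the per-set comparison p-values as a wide TSV
#'
#' One row per gene set, one column per comparison (the supplementary-table
#' layout).
#'
#' @param x An `mgsea_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_comparisons_tsv <- function(x, path) {
  wide <- tidyr::pivot_wider(
    dplyr::select(x$comparisons, "set", "comparison", "p_value"),
    names_from = "comparison", values_from = "p_value"
  )
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

#' Write the per-set combinatorial patterns as JSON
#'
#' @param x An `mgsea_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_patterns_json <- function(x, path) {
  recs <- lapply(seq_len(nrow(x$patterns)), function(i) {
    p <- x$patterns[i, ]
    list(
      set = p$set,
      K = p$K,
      pattern = p$pattern,
      dominant = as.list(p$dominant[[1L]]),
      redundant_pairs = apply(p$redundant[[1L]], 1L, function(r) paste(r, collapse = "|"))
    )
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
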