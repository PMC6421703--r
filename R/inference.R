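# Curve comparison and combinatorial pattern classification.

curve_label <- function(curve) {
  kind <- attr(curve, "kind")
  feats <- attr(curve, "features")
  perm <- attr(curve, "permuted")
  if (kind == "null") return("null")
  if (kind %in% c("conditional_expected", "mc_mean") && !is.na(perm)) {
    return(paste0("C(", perm, "|", paste(feats, collapse = ","), ")"))
  }
  paste0("C(", paste(feats, collapse = ","), ")")
}

#' Compare two walk curves by a one-sided Mann-Whitney U test
#'
#' Treats the two normalized curves as samples of values over a shared knot
#' grid and tests whether curve A is stochastically larger than curve B
#' (i.e. A deviates positively from B). The normal approximation with tie
#' and continuity correction is used; with fewer than 30 knots and no ties
#' the exact U distribution is used instead. Identical curves give p = 0.5
#' and are never significant.
#'
#' @param curve_a,curve_b Normalized `walk_curve`s on the same knot grid
#'   with the same N and K.
#' @param threshold Significance threshold for the `significant` flag
#'   (default 1e-10).
#' @return One-row tibble: `curve_a`, `curve_b` (labels), `statistic` (U),
#'   `p_value`, `significant`.
#' @export
compare_walks <- function(curve_a, curve_b, threshold = 1e-10) {
  if (!isTRUE(attr(curve_a, "normalized")) || !isTRUE(attr(curve_b, "normalized"))) {
    abort("both curves must be normalized (see normalize_walk)")
  }
  if (!identical(curve_a$rank, curve_b$rank)) {
    abort("curves are evaluated on different knot grids")
  }
  if (attr(curve_a, "N") != attr(curve_b, "N") || attr(curve_a, "K") != attr(curve_b, "K")) {
    abort("curves have mismatched N or K")
  }
  if (threshold <= 0 || threshold >= 1) abort("threshold must lie in (0, 1)")
  res <- mwu_greater(curve_a$value, curve_b$value)
  tibble(
    curve_a = curve_label(curve_a),
    curve_b = curve_label(curve_b),
    statistic = res$statistic,
    p_value = res$p_value,
    significant = res$p_value <= threshold
  )
}

#' Enumerate the walk comparisons for m platforms
#'
#' Two families of one-sided comparisons drive the classification:
#' every nonempty platform subset's (joint) walk against the null line, and,
#' for every subset of size >= 2 and every member platform i, the subset's
#' joint walk against the conditional walk that randomises i. For three
#' platforms this yields exactly 16 comparisons; in general
#' `2^m - 1 + sum_{t>=2} C(m,t) * t`.
#'
#' @param features Character vector of platform names (m >= 2).
#' @return Tibble with columns `comparison` (label), `kind`
#'   (`"vs_null"` or `"vs_conditional"`), `subset` (list of platform name
#'   vectors) and `permuted` (randomised platform, `NA` for null
#'   comparisons).
#' @examples
#' enumerate_comparisons(c("cnv", "met", "mrna"))
#' @export
enumerate_comparisons <- function(features) {
  m <- length(features)
  if (m < 2L) abort("need at least 2 features")
  if (anyDuplicated(features) > 0L) abort("feature names must be unique")
  subsets <- unlist(
    lapply(seq_len(m), function(t) utils::combn(features, t, simplify = FALSE)),
    recursive = FALSE
  )
  null_rows <- tibble(
    comparison = vapply(subsets, function(s) paste0("C(", paste(s, collapse = ","), ") vs null"), character(1L)),
    kind = "vs_null",
    subset = subsets,
    permuted = NA_character_
  )
  cond <- list()
  for (s in subsets[lengths(subsets) >= 2L]) {
    for (i in s) {
      cond[[length(cond) + 1L]] <- list(subset = s, permuted = i)
    }
  }
  cond_rows <- tibble(
    comparison = vapply(cond, function(cc) {
      paste0(
        "C(", paste(cc$subset, collapse = ","), ") vs C(",
        cc$permuted, "|", paste(setdiff(cc$subset, cc$permuted), collapse = ","), ")"
      )
    }, character(1L)),
    kind = "vs_conditional",
    subset = lapply(cond, `[[`, "subset"),
    permuted = vapply(cond, `[[`, character(1L), "permuted")
  )
  dplyr::bind_rows(null_rows, cond_rows)
}

subset_key <- function(s) paste(sort(s), collapse = "\r")

#' Classify a gene set's combinatorial enrichment pattern
#'
#' Applies the dominance and redundancy rules to a full table of comparison
#' results (one gene set):
#' * platform i is **dominant** when its univariate walk beats the null
#'   significantly and, for every subset containing i, the subset's joint
#'   walk significantly beats the conditional walk randomising i — its
#'   enrichment information is not subsumed by any other platform subset;
#' * platforms i and j are **redundant** when both are univariately
#'   significant yet no joint walk of a subset containing both
#'   significantly beats either of the conditional walks randomising i or
#'   j — their information is interchangeable. Redundancy is closed
#'   transitively.
#'
#' @param results Tibble of comparison results covering every row of
#'   [enumerate_comparisons()] for `features`: columns `kind`, `subset`,
#'   `permuted`, `p_value`.
#' @param features Character vector of platform names.
#' @param threshold Significance threshold applied to `p_value`.
#' @return One-row tibble: `dominant` (list: character vector of dominant
#'   platforms), `redundant` (list: two-column matrix of redundant pairs,
#'   transitively closed), `univariate_significant` (list: named logical),
#'   and `pattern` (label of the exact dominant set, `"none"` if empty).
#' @export
classify_pattern <- function(results, features, threshold = 1e-10) {
  specs <- enumerate_comparisons(features)
  res_key <- paste(results$kind, vapply(results$subset, subset_key, character(1L)),
    ifelse(is.na(results$permuted), "", results$permuted),
    sep = "|"
  )
  sig_of <- function(kind, subset, permuted = NA_character_) {
    key <- paste(kind, subset_key(subset), ifelse(is.na(permuted), "", permuted), sep = "|")
    i <- match(key, res_key)
    if (is.na(i)) {
      lab <- if (kind == "vs_null") {
        paste0("C(", paste(subset, collapse = ","), ") vs null")
      } else {
        paste0(
          "C(", paste(subset, collapse = ","), ") vs C(", permuted, "|",
          paste(setdiff(subset, permuted), collapse = ","), ")"
        )
      }
      abort(paste0("missing comparison result: ", lab))
    }
    results$p_value[i] <= threshold
  }
  # check coverage up front so errors name the first missing spec
  for (i in seq_len(nrow(specs))) {
    sig_of(specs$kind[i], specs$subset[[i]], specs$permuted[i])
  }
  multi <- specs$subset[!duplicated(vapply(specs$subset, subset_key, character(1L)))]
  multi <- multi[lengths(multi) >= 2L]

  uni_sig <- vapply(features, function(f) sig_of("vs_null", f), logical(1L))
  dominant <- vapply(features, function(f) {
    if (!uni_sig[[f]]) return(FALSE)
    all(vapply(
      multi[vapply(multi, function(s) f %in% s, logical(1L))],
      function(s) sig_of("vs_conditional", s, f), logical(1L)
    ))
  }, logical(1L))

  pairs <- if (length(features) >= 2L) utils::combn(features, 2L, simplify = FALSE) else list()
  redundant_raw <- vapply(pairs, function(pr) {
    if (!uni_sig[[pr[1L]]] || !uni_sig[[pr[2L]]]) return(FALSE)
    containing <- multi[vapply(multi, function(s) all(pr %in% s), logical(1L))]
    !any(vapply(containing, function(s) {
      sig_of("vs_conditional", s, pr[1L]) || sig_of("vs_conditional", s, pr[2L])
    }, logical(1L)))
  }, logical(1L))

  # transitive closure over the redundancy graph
  comp <- stats::setNames(seq_along(features), features)
  for (i in which(redundant_raw)) {
    pr <- pairs[[i]]
    old <- comp[pr[2L]]
    comp[comp == old] <- comp[pr[1L]]
  }
  redundant <- do.call(rbind, Filter(Negate(is.null), lapply(pairs, function(pr) {
    if (comp[pr[1L]] == comp[pr[2L]] && any(redundant_raw)) pr else NULL
  })))
  # only pairs inside a component that actually contains a redundant edge
  if (!is.null(redundant)) {
    edge_comps <- unique(comp[unlist(pairs[redundant_raw])])
    keep <- apply(redundant, 1L, function(pr) comp[pr[1L]] %in% edge_comps)
    redundant <- redundant[keep, , drop = FALSE]
  } else {
    redundant <- matrix(character(0L), ncol = 2L)
  }
  colnames(redundant) <- c("feature_a", "feature_b")

  dom_set <- features[dominant]
  tibble(
    dominant = list(dom_set),
    redundant = list(redundant),
    univariate_significant = list(uni_sig),
    pattern = if (length(dom_set) == 0L) "none" else paste(dom_set, collapse = "&")
  )
}
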