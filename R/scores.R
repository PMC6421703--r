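#' Rank-transform a numeric vector to empirical CDF values
#'
#' Maps each non-missing value to `rank / n`, where `n` is the number of
#' non-missing values and tied values share the mean rank. Output lies in
#' (0, 1]; missing entries stay missing. This is the standard preprocessing
#' applied to each probe or gene across samples so that heterogeneous
#' platform units become comparable relative orders.
#'
#' @param x Numeric vector, possibly with `NA`.
#' @return Numeric vector of the same length.
#' @examples
#' rank_to_cdf(c(3, 1, 2))   # 1, 1/3, 2/3
#' rank_to_cdf(c(5, 5))      # 0.75, 0.75
#' @export
rank_to_cdf <- function(x) {
  if (!is.numeric(x)) abort("rank_to_cdf expects a numeric vector")
  n <- sum(!is.na(x))
  if (n == 0L) abort("rank_to_cdf: all values are missing")
  rank(x, ties.method = "average", na.last = "keep") / n
}

#' Average probe-level values into gene-level values
#'
#' For each sample, a gene's value is the arithmetic mean of the non-missing
#' values of its probes; it is missing only when all probes are missing.
#' Probes absent from `probe_to_gene` are dropped.
#'
#' @param mat Tibble/data frame of probe measurements: first column sample
#'   identifiers, remaining columns one probe each.
#' @param probe_to_gene Tibble/data frame with columns `probe` and `gene`;
#'   each probe may map to at most one gene.
#' @return A tibble with the same sample column and one column per gene.
#' @export
aggregate_probes <- function(mat, probe_to_gene) {
  stopifnot(is.data.frame(mat), ncol(mat) >= 2L)
  stopifnot(is.data.frame(probe_to_gene), all(c("probe", "gene") %in% names(probe_to_gene)))
  if (nrow(probe_to_gene) == 0L) abort("empty probe-to-gene mapping")
  if (anyDuplicated(probe_to_gene$probe) > 0L) {
    abort("a probe maps to more than one gene in probe_to_gene")
  }
  sample_col <- names(mat)[1L]
  map <- probe_to_gene[probe_to_gene$probe %in% names(mat)[-1L], , drop = FALSE]
  if (nrow(map) == 0L) abort("no probe in the mapping matches a matrix column")
  genes <- sort(unique(map$gene))
  vals <- lapply(genes, function(g) {
    probes <- map$probe[map$gene == g]
    block <- as.matrix(mat[, probes, drop = FALSE])
    v <- rowMeans(block, na.rm = TRUE)
    v[is.nan(v)] <- NA_real_
    v
  })
  names(vals) <- genes
  dplyr::bind_cols(mat[, sample_col, drop = FALSE], as_tibble(vals))
}

#' Drop genes dominated by invalid values
#'
#' A gene is removed when more than half of its sample values are invalid,
#' where invalid means missing or exactly zero (platform pipelines emit zero
#' for absent measurements as often as `NA`).
#'
#' @param mat Tibble of a samples-by-genes feature matrix; first column
#'   sample identifiers.
#' @return The matrix with offending gene columns removed.
#' @export
filter_invalid_genes <- function(mat) {
  stopifnot(is.data.frame(mat), ncol(mat) >= 2L)
  n <- nrow(mat)
  keep <- vapply(mat[-1L], function(v) sum(is.na(v) | v == 0, na.rm = FALSE) <= n / 2, logical(1L))
  keep[is.na(keep)] <- FALSE
  mat[, c(TRUE, keep), drop = FALSE]
}

#' Mutual information between a continuous feature and categorical labels
#'
#' Estimates `I(X; Y) = sum_i P(y = i) * integral p(x|y=i) log(p(x|y=i)/p(x)) dx`
#' in nats. Each class-conditional density is a Gaussian kernel density
#' estimate with Silverman's-rule bandwidth; the marginal is the
#' class-fraction-weighted mixture of the class-conditional estimates, which
#' keeps the plug-in estimate consistent (a separately bandwidthed marginal
#' inflates the divergence for well-separated classes). The class mass
#' function is the empirical class fraction, and the integral is a trapezoid
#' rule over an equally spaced grid spanning the observed range plus a
#' padding fraction on each side. Samples with a missing feature value are
#' excluded from both the densities and the class fractions. The result is
#' clipped at zero (trapezoid error can push it slightly negative).
#'
#' @param x Numeric feature vector (one value per sample, `NA` allowed).
#' @param labels Categorical labels aligned with `x`; at least 2 distinct
#'   classes, each with at least 2 non-missing feature values.
#' @param n_grid Number of integration grid points (minimum 32, default 512).
#' @param padding Fraction of the observed range added on each side of the
#'   integration interval (default 0.1).
#' @param bw Bandwidth rule: `"nrd0"` (Silverman, the default) or `"SJ"`
#'   (Sheather-Jones, less boundary bias for sharply binned features). A
#'   class with zero spread falls back to a narrow kernel (1% of the pooled
#'   standard deviation) so point masses stay near-disjoint.
#' @return Mutual information in nats (non-negative scalar).
#' @examples
#' set.seed(1)
#' x <- c(rnorm(200, 0), rnorm(200, 3))
#' y <- rep(c("a", "b"), each = 200)
#' mutual_information(x, y)   # close to ln 2 for well-separated classes
#' @export
mutual_information <- function(x, labels, n_grid = 512L, padding = 0.1,
                               bw = c("nrd0", "SJ")) {
  bw <- match.arg(bw)
  if (length(x) != length(labels)) abort("x and labels must have the same length")
  if (n_grid < 32L) abort("n_grid must be >= 32")
  if (padding < 0) abort("padding must be >= 0")
  keep <- !is.na(x)
  x <- x[keep]
  labels <- as.character(labels[keep])
  if (anyNA(labels)) abort("labels must be non-missing")
  classes <- sort(unique(labels))
  if (length(classes) < 2L) abort("need at least 2 distinct labels")
  counts <- table(factor(labels, levels = classes))
  small <- names(counts)[counts < 2L]
  if (length(small) > 0L) {
    abort(paste0("class '", small[1L], "' has fewer than 2 non-missing feature values"))
  }
  sd_all <- stats::sd(x)
  if (!is.finite(sd_all)) abort("non-finite feature values")
  if (sd_all == 0) return(0)

  rng <- range(x)
  pad <- padding * diff(rng)
  grid <- seq(rng[1L] - pad, rng[2L] + pad, length.out = n_grid)
  bw_fun <- switch(bw, nrd0 = stats::bw.nrd0, SJ = stats::bw.SJ)
  kde <- function(v) {
    # degenerate within-class spread: fall back to a narrow kernel relative
    # to the pooled spread so point masses stay near-disjoint (bw.nrd0's
    # own zero-variance fallback would smear them over unit width)
    h <- if (stats::sd(v) > 0) bw_fun(v) else 0
    if (!is.finite(h) || h <= 0) h <- 0.01 * sd_all
    d <- rowMeans(stats::dnorm(outer(grid, v, "-") / h)) / h
    if (any(!is.finite(d))) abort("non-finite kernel density estimate")
    d
  }
  p_y <- as.numeric(counts) / length(x)
  p_xy <- lapply(classes, function(cl) kde(x[labels == cl]))
  p_x <- Reduce(`+`, Map(`*`, p_y, p_xy))
  dx <- grid[2L] - grid[1L]
  mi <- 0
  for (i in seq_along(classes)) {
    f <- ifelse(p_xy[[i]] > 0 & p_x > 0, p_xy[[i]] * log(p_xy[[i]] / p_x), 0)
    mi <- mi + p_y[i] * sum((f[-1L] + f[-n_grid]) / 2) * dx
  }
  max(mi, 0)
}

#' Per-gene mutual-information scores for a feature matrix
#'
#' Applies [mutual_information()] to every gene column of a samples-by-genes
#' matrix against per-sample labels.
#'
#' @param mat Tibble of feature values; first column sample identifiers.
#' @param labels Tibble with columns `sample` and `label`, or a vector
#'   aligned with the rows of `mat`.
#' @inheritParams mutual_information
#' @return Tibble with columns `gene` and `score` (nats).
#' @export
mi_scores <- function(mat, labels, n_grid = 512L, padding = 0.1,
                      bw = c("nrd0", "SJ")) {
  bw <- match.arg(bw)
  stopifnot(is.data.frame(mat), ncol(mat) >= 2L)
  if (is.data.frame(labels)) {
    stopifnot(all(c("sample", "label") %in% names(labels)))
    idx <- match(mat[[1L]], labels$sample)
    if (anyNA(idx)) abort("some samples in the matrix have no label")
    lab <- labels$label[idx]
  } else {
    if (length(labels) != nrow(mat)) abort("labels must align with matrix rows")
    lab <- labels
  }
  genes <- names(mat)[-1L]
  tibble(
    gene = genes,
    score = vapply(
      genes,
      function(g) mutual_information(mat[[g]], lab, n_grid = n_grid, padding = padding, bw = bw),
      numeric(1L)
    )
  )
}

#' Build a universe from the union of top-ranking genes across platforms
#'
#' Genes enter the universe in the order in which they first appear in any
#' platform's descending-score ranking (their best rank across platforms,
#' ties broken by ascending gene identifier); only genes scored on every
#' platform are eligible. The smallest prefix depth whose union reaches
#' `target_size` determines the cut, and the union is truncated exactly to
#' `target_size` by dropping the last-added genes.
#'
#' @param score_table Tibble with a `gene` column and one numeric score
#'   column per platform.
#' @param target_size Desired universe size.
#' @return Character vector of `target_size` gene identifiers, in entry
#'   order.
#' @export
build_universe <- function(score_table, target_size) {
  stopifnot(is.data.frame(score_table), "gene" %in% names(score_table))
  platforms <- setdiff(names(score_table), "gene")
  if (length(platforms) == 0L) abort("score table has no platform columns")
  if (anyDuplicated(score_table$gene) > 0L) abort("duplicate gene identifiers in score table")
  valid <- stats::complete.cases(score_table[platforms])
  if (target_size > sum(valid)) {
    abort(paste0(
      "target_size (", target_size, ") exceeds the ", sum(valid),
      " genes scored on every platform"
    ))
  }
  # best (smallest) rank of each all-platform-valid gene across platforms;
  # ranks are computed within each platform over all genes scored there
  best <- rep(Inf, nrow(score_table))
  for (p in platforms) {
    s <- score_table[[p]]
    scored <- which(!is.na(s))
    ord <- scored[order(-s[scored], score_table$gene[scored])]
    pos <- rep(Inf, nrow(score_table))
    pos[ord] <- seq_along(ord)
    best <- pmin(best, pos)
  }
  cand <- which(valid)
  cand <- cand[order(best[cand], score_table$gene[cand])]
  score_table$gene[cand[seq_len(target_size)]]
}

#' Read a per-gene score table from TSV
#'
#' Expects a header `gene<TAB>platform1<TAB>platform2...`; empty fields and
#' `NA` are treated as missing.
#'
#' @param path Path to the TSV file.
#' @return A tibble with a character `gene` column and numeric platform
#'   columns.
#' @export
read_score_table <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    gene = readr::col_character(),
    .default = readr::col_double()
  ), na = c("", "NA"), progress = FALSE)
  if (!"gene" %in% names(tab)) abort("score table must have a 'gene' column")
  tab
}
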