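#' Probability that a random prefix contributes extra genes
#'
#' When one platform's ranking is randomised while the top prefixes of the
#' other platforms stay fixed (covering `n_fixed` distinct genes), the number
#' of new genes contributed by the random platform's top `n` is
#' hypergeometric:
#' `P(n_extra | n) = C(N - n_fixed, n_extra) * C(n_fixed, n - n_extra) / C(N, n)`.
#' Computed in log space; impossible combinations contribute probability 0.
#'
#' @param N Universe size.
#' @param n_fixed Number of distinct genes covered by the fixed prefixes.
#' @param n Prefix depth of the randomised platform.
#' @param n_extra Number of newly contributed genes (vectorised); must lie in
#'   `0..min(n, N - n_fixed)`.
#' @return Probabilities, one per `n_extra`.
#' @export
p_n_extra <- function(N, n_fixed, n, n_extra) {
  if (n_fixed < 0 || n_fixed > N) abort("need 0 <= n_fixed <= N")
  if (n < 0 || n > N) abort("need 0 <= n <= N")
  if (any(n_extra < 0 | n_extra > min(n, N - n_fixed))) {
    abort("n_extra out of range 0..min(n, N - n_fixed)")
  }
  exp(lchoose(N - n_fixed, n_extra) + lchoose(n_fixed, n - n_extra) - lchoose(N, n))
}

#' Probability that extra genes include gene set members
#'
#' Conditioned on `n_extra` new genes entering the union from the randomised
#' platform, the number of gene set members among them is again
#' hypergeometric: `k_extra` members are drawn from the `K - k_fixed`
#' members still outside the fixed union, the rest from the
#' `N - n_fixed - K + k_fixed` non-members outside it.
#'
#' @param N Universe size.
#' @param K Gene set size.
#' @param n_fixed Genes covered by the fixed prefixes.
#' @param k_fixed Gene set members among them (`0..min(K, n_fixed)`).
#' @param n_extra Newly contributed genes.
#' @param k_extra Members among the new genes (vectorised); must lie in
#'   `0..min(n_extra, K - k_fixed)`.
#' @return Probabilities, one per `k_extra`.
#' @export
p_k_extra <- function(N, K, n_fixed, k_fixed, n_extra, k_extra) {
  if (K < 0 || K > N) abort("need 0 <= K <= N")
  if (n_fixed < 0 || n_fixed > N) abort("need 0 <= n_fixed <= N")
  if (k_fixed < 0 || k_fixed > min(K, n_fixed)) abort("need 0 <= k_fixed <= min(K, n_fixed)")
  if (K - k_fixed > N - n_fixed) {
    abort("inconsistent geometry: more members than genes outside the fixed union")
  }
  if (n_extra < 0 || n_extra > N - n_fixed) abort("need 0 <= n_extra <= N - n_fixed")
  if (any(k_extra < 0 | k_extra > min(n_extra, K - k_fixed))) {
    abort("k_extra out of range 0..min(n_extra, K - k_fixed)")
  }
  exp(
    lchoose(K - k_fixed, k_extra) +
      lchoose(N - n_fixed - K + k_fixed, n_extra - k_extra) -
      lchoose(N - n_fixed, n_extra)
  )
}

# Fixed-union geometry shared by the conditional walk routines: for each
# rank x, how many distinct genes (and members) the fixed prefixes cover.
fixed_union_counts <- function(fixed_lists, members) {
  fixed_lists <- if (inherits(fixed_lists, "ranked_list")) list(fixed_lists) else fixed_lists
  pos <- position_matrix(fixed_lists)
  genes <- check_same_universe(fixed_lists)
  hit <- members_in_universe(members, genes)
  entries <- entry_ranks(pos)
  N <- length(genes)
  list(
    N = N, K = sum(hit),
    n_fixed = cum_entries(entries, N),
    k_fixed = cum_entries(entries[hit], N),
    entries = entries, hit = hit,
    features = vapply(fixed_lists, function(rl) attr(rl, "feature") %||% "feature", character(1L))
  )
}

#' Expected conditional walk (analytic)
#'
#' The conditional walk `y_{Fi | rest}(n)` is the expected joint walk when
#' platform Fi's ranking is replaced by a uniformly random permutation while
#' the other platforms' rankings stay fixed. At prefix depth n the fixed
#' prefixes cover `n_fixed(n)` genes of which `k_fixed(n)` are members, and
#' the expected extra members contributed by the random prefix follow the
#' nested hypergeometric laws of [p_n_extra()] and [p_k_extra()]:
#'
#' `y(n) = k_fixed + sum_{n_extra} sum_{k_extra} P(n_extra|n) P(k_extra|n_extra) k_extra`
#'
#' The inner sum equals the hypergeometric mean
#' `n_extra (K - k_fixed) / (N - n_fixed)` and the outer sum then equals
#' `n (N - n_fixed) / N` times that rate, so the default method evaluates
#' the closed form `k_fixed + n (K - k_fixed) / N`. `method = "sum"`
#' (explicit outer sum) and `method = "exact"` (full double sum) are
#' mathematically identical and retained for verification.
#'
#' Only a single randomised platform is supported: the union of two or more
#' permuted prefixes has no comparably simple law, so such conditionals are
#' rejected.
#'
#' @param fixed_lists One `ranked_list` or a list of them (the platforms
#'   held fixed).
#' @param members Character vector of gene set members.
#' @param knots Integer rank grid to evaluate at (default full 1..N).
#' @param method `"analytic"` (default), `"sum"`, or `"exact"`.
#' @param permuted Name of the randomised platform (label only); must not be
#'   one of the fixed platforms. Supplying more than one name is an error.
#' @return A raw `walk_curve` of kind `"conditional_expected"`.
#' @export
expected_conditional_walk <- function(fixed_lists, members, knots = NULL,
                                      method = c("analytic", "sum", "exact"),
                                      permuted = NA_character_) {
  method <- match.arg(method)
  if (length(permuted) > 1L) {
    abort(paste0(
      "conditional walks support exactly one randomised platform; ",
      "the union of several permuted prefixes has no closed-form law"
    ))
  }
  fu <- fixed_union_counts(fixed_lists, members)
  if (!is.na(permuted) && permuted %in% fu$features) {
    abort(paste0("permuted platform '", permuted, "' is among the fixed platforms"))
  }
  N <- fu$N
  K <- fu$K
  knots <- knots %||% seq_len(N)
  if (any(knots < 1L | knots > N)) abort("knots must lie in 1..N")
  nf <- fu$n_fixed[knots]
  kf <- fu$k_fixed[knots]
  vals <- switch(method,
    analytic = kf + knots * (K - kf) / N,
    sum = vapply(seq_along(knots), function(i) {
      n <- knots[i]
      if (N - nf[i] == 0L) return(as.numeric(kf[i]))
      ne <- 0:min(n, N - nf[i])
      kf[i] + sum(p_n_extra(N, nf[i], n, ne) * ne * (K - kf[i]) / (N - nf[i]))
    }, numeric(1L)),
    exact = vapply(seq_along(knots), function(i) {
      n <- knots[i]
      if (N - nf[i] == 0L) return(as.numeric(kf[i]))
      ne <- 0:min(n, N - nf[i])
      pn <- p_n_extra(N, nf[i], n, ne)
      inner <- vapply(ne, function(e) {
        ke <- 0:min(e, K - kf[i])
        sum(p_k_extra(N, K, nf[i], kf[i], e, ke) * ke)
      }, numeric(1L))
      kf[i] + sum(pn * inner)
    }, numeric(1L))
  )
  new_walk_curve(
    knots, vals,
    N = N, K = K, kind = "conditional_expected",
    features = fu$features, permuted = permuted
  )
}

#' Monte-Carlo conditional walk
#'
#' Estimates the conditional walk by averaging the joint walk over `n_perm`
#' uniformly random orderings of the randomised platform, the fixed
#' platforms' rankings held at their empirical order. Serves as the
#' simulation oracle for [expected_conditional_walk()].
#'
#' @inheritParams expected_conditional_walk
#' @param n_perm Number of random permutations (>= 1).
#' @param seed Optional integer seed; fixing it makes the output
#'   bitwise-reproducible.
#' @param perms Optional N x n_perm integer matrix of pre-specified
#'   permutations (each column a permutation of 1..N giving every gene's
#'   rank in the randomised list); used for deterministic testing.
#' @return A raw `walk_curve` of kind `"mc_mean"` with an `se` column (per
#'   knot standard error of the mean).
#' @export
mc_conditional_walk <- function(fixed_lists, members, n_perm, seed = NULL,
                                knots = NULL, permuted = NA_character_,
                                perms = NULL) {
  if (n_perm < 1L) abort("n_perm must be >= 1")
  fu <- fixed_union_counts(fixed_lists, members)
  N <- fu$N
  knots <- knots %||% seq_len(N)
  if (any(knots < 1L | knots > N)) abort("knots must lie in 1..N")
  if (!is.null(perms)) stopifnot(nrow(perms) == N, ncol(perms) == n_perm)
  hit_idx <- which(fu$hit)
  fixed_entries <- fu$entries
  draw <- function(b) {
    rand_pos <- if (is.null(perms)) sample.int(N) else perms[, b]
    entry <- pmin(fixed_entries, rand_pos)
    cumsum(tabulate(entry[hit_idx], nbins = N))[knots]
  }
  vals <- run_seeded(seed, vapply(seq_len(n_perm), draw, numeric(length(knots))))
  vals <- matrix(vals, nrow = length(knots))
  mn <- rowMeans(vals)
  se <- if (n_perm > 1L) apply(vals, 1L, stats::sd) / sqrt(n_perm) else rep(0, length(knots))
  new_walk_curve(
    knots, mn,
    N = N, K = fu$K, kind = "mc_mean",
    features = fu$features, permuted = permuted, se = se
  )
}
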