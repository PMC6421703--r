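make_curve <- function(values, N, K, kind = "empirical", features = "f",
                       ranks = seq_along(values), normalized = TRUE, permuted = NA) {
  w <- mgsea:::new_walk_curve(ranks, values,
    N = N, K = K, kind = kind,
    features = features, normalized = normalized, permuted = permuted
  )
  w
}

test_that("a curve compared with itself is never significant", {
  v <- pmin(seq_len(100) / 40, 1)
  a <- make_curve(v, 100, 40)
  res <- compare_walks(a, a, threshold = 0.05)
  expect_equal(res$p_value, 0.5, tolerance = 0.02)
  expect_false(res$significant)
})

test_that("a steep staircase crushes the diagonal at 500 knots", {
  knots <- seq(2, 1000, by = 2)
  a <- make_curve(pmin(knots / 50, 1), 1000, 50, ranks = knots)
  b <- make_curve(knots / 1000, 1000, 50, kind = "null", features = "null", ranks = knots)
  res <- compare_walks(a, b)
  expect_lt(res$p_value, 1e-10)
  expect_true(res$significant)
  # independent check of the one-sided normal-approximation p-value
  expect_equal(res$p_value, wilcox_greater_p(a$value, b$value), tolerance = 1e-6)
})

test_that("a curve strictly below its baseline is one-sidedly non-significant", {
  knots <- 1:200
  a <- make_curve(knots / 400, 200, 50, ranks = knots)
  b <- make_curve(knots / 200, 200, 50, kind = "null", features = "null", ranks = knots)
  res <- compare_walks(a, b, threshold = 0.05)
  expect_gt(res$p_value, 0.99)
  expect_false(res$significant)
})

test_that("the MWU backend matches stats::wilcox.test in both branches", {
  withr::with_seed(17, {
    # normal-approximation branch (n >= 30)
    for (i in 1:5) {
      x <- stats::runif(60)
      y <- stats::runif(60) - 0.1 * i / 5
      expect_equal(
        mgsea:::mwu_greater(x, y)$p_value,
        wilcox_greater_p(x, y, exact = FALSE),
        tolerance = 1e-10
      )
    }
    # exact branch (small, tie-free)
    for (i in 1:5) {
      x <- stats::rnorm(12)
      y <- stats::rnorm(15) - 0.3
      expect_equal(
        mgsea:::mwu_greater(x, y)$p_value,
        wilcox_greater_p(x, y, exact = TRUE),
        tolerance = 1e-12
      )
    }
  })
})

test_that("compare_walks validates grids and normalization", {
  a <- make_curve((1:50) / 50, 50, 10)
  b <- make_curve((1:40) / 40, 50, 10, ranks = 1:40)
  expect_error(compare_walks(a, b), "different knot grids")
  raw <- make_curve(1:50, 50, 10, normalized = FALSE)
  expect_error(compare_walks(raw, a), "normalized")
  c2 <- make_curve((1:50) / 50, 50, 20)
  expect_error(compare_walks(a, c2), "mismatched N or K")
})

test_that("three platforms yield exactly the 16 canonical comparisons", {
  specs <- enumerate_comparisons(c("1", "2", "3"))
  expect_equal(nrow(specs), 16L)
  expected <- c(
    "C(1) vs null", "C(2) vs null", "C(3) vs null",
    "C(1,2) vs null", "C(2,3) vs null", "C(1,3) vs null", "C(1,2,3) vs null",
    "C(1,2) vs C(1|2)", "C(1,2) vs C(2|1)",
    "C(2,3) vs C(2|3)", "C(2,3) vs C(3|2)",
    "C(1,3) vs C(1|3)", "C(1,3) vs C(3|1)",
    "C(1,2,3) vs C(1|2,3)", "C(1,2,3) vs C(2|1,3)", "C(1,2,3) vs C(3|1,2)"
  )
  expect_setequal(specs$comparison, expected)
})

test_that("comparison counts follow the subset/conditional composition", {
  expect_equal(nrow(enumerate_comparisons(c("a", "b"))), 5L) # 3 vs null + 2 conditionals
  # m = 4: every nonempty subset vs null, plus one conditional per (subset
  # of size >= 2, member) pair — counted independently here by enumeration
  m <- 4
  n_subsets <- sum(choose(m, 1:m))
  n_cond <- sum(vapply(2:m, function(t) choose(m, t) * t, numeric(1)))
  expect_equal(nrow(enumerate_comparisons(letters[1:4])), n_subsets + n_cond)
  expect_error(enumerate_comparisons("solo"), "at least 2")
})

# build a results table for classify_pattern from a named p-value list
results_from_p <- function(features, p) {
  specs <- enumerate_comparisons(features)
  specs$p_value <- vapply(specs$comparison, function(cc) p[[cc]], numeric(1))
  specs
}

test_that("classification applies the dominance rule across all contexts", {
  feats <- c("A", "B", "C")
  specs <- enumerate_comparisons(feats)
  p <- stats::setNames(rep(1, nrow(specs)), specs$comparison)
  # A univariately significant and adds information in every context
  p["C(A) vs null"] <- 1e-20
  p["C(A,B) vs C(A|B)"] <- 1e-20
  p["C(A,C) vs C(A|C)"] <- 1e-20
  p["C(A,B,C) vs C(A|B,C)"] <- 1e-20
  out <- classify_pattern(results_from_p(feats, as.list(p)), feats, threshold = 1e-10)
  expect_equal(out$dominant[[1]], "A")
  expect_equal(out$pattern, "A")
  # drop one conditioning context: A is subsumed there, no longer dominant
  p["C(A,B,C) vs C(A|B,C)"] <- 1
  out2 <- classify_pattern(results_from_p(feats, as.list(p)), feats, threshold = 1e-10)
  expect_equal(out2$pattern, "none")
})

test_that("redundancy requires univariate significance and closes transitively", {
  feats <- c("A", "B", "C")
  specs <- enumerate_comparisons(feats)
  # all univariate walks significant, no conditional comparison significant:
  # every pair redundant
  p <- stats::setNames(rep(1, nrow(specs)), specs$comparison)
  p[grepl("^C\\([A-C]\\) vs null$", names(p))] <- 1e-20
  out <- classify_pattern(results_from_p(feats, as.list(p)), feats, threshold = 1e-10)
  red <- out$redundant[[1]]
  expect_equal(nrow(red), 3L)
  expect_equal(out$pattern, "none")
  # with C univariately non-significant only (A, B) remain redundant
  p["C(C) vs null"] <- 1
  out2 <- classify_pattern(results_from_p(feats, as.list(p)), feats, threshold = 1e-10)
  expect_equal(unname(as.vector(out2$redundant[[1]])), c("A", "B"))
})

test_that("classification errors name the first missing comparison", {
  feats <- c("A", "B")
  specs <- enumerate_comparisons(feats)
  specs$p_value <- 1
  expect_error(
    classify_pattern(specs[-2, ], feats, threshold = 0.05),
    "missing comparison result: C\\(B\\) vs null"
  )
})

test_that("lowering the threshold never adds dominant features", {
  withr::with_seed(23, {
    feats <- c("A", "B", "C")
    specs <- enumerate_comparisons(feats)
    for (i in 1:20) {
      pv <- as.list(stats::setNames(10^stats::runif(nrow(specs), -15, 0), specs$comparison))
      res <- results_from_p(feats, pv)
      dom_loose <- classify_pattern(res, feats, threshold = 1e-2)$dominant[[1]]
      dom_tight <- classify_pattern(res, feats, threshold = 1e-8)$dominant[[1]]
      expect_true(all(dom_tight %in% dom_loose))
    }
  })
})

test_that("a platform duplicated byte-for-byte never tests dominant against its copy", {
  withr::with_seed(67, {
    for (i in 1:10) {
      N <- 300
      tab <- random_score_table(N, platforms = "x1", seed = 500 + i)
      tab$copy <- tab$x1
      strength <- stats::runif(1, 5, 30)
      members <- tab$gene[stats::runif(N) < 1 / (1 + exp(-strength * (tab$x1 - 0.5)))]
      if (length(members) < 5 || length(members) > N - 5) next
      fit <- mgsea(tab, list(s = members), n_knots = N, threshold = 1e-6)
      expect_equal(fit$patterns$pattern, "none")
      uni <- fit$patterns$univariate_significant[[1]]
      if (all(uni)) {
        expect_equal(nrow(fit$patterns$redundant[[1]]), 1L)
      }
    }
  })
})
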