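test_that("p_n_extra matches exhaustive enumeration on a toy universe", {
  # N = 5, n_fixed = 2, n = 2: enumerate all C(5,2) = 10 draws directly
  draws <- utils::combn(5, 2, simplify = FALSE)
  n_extra_of <- vapply(draws, function(d) sum(d > 2), numeric(1)) # genes 3,4,5 are "outside"
  expected <- table(factor(n_extra_of, levels = 0:2)) / length(draws)
  expect_equal(p_n_extra(5, 2, 2, 0:2), as.numeric(expected))
  expect_equal(p_n_extra(5, 2, 2, 0:2), c(1, 6, 3) / 10)
})

test_that("p_n_extra handles saturated fixed prefixes and validates ranges", {
  expect_equal(p_n_extra(10, 10, 4, 0), 1)
  expect_error(p_n_extra(10, 11, 4, 0), "n_fixed")
  expect_error(p_n_extra(10, 2, 4, 5), "out of range")
})

test_that("p_k_extra matches exhaustive enumeration and its edge cases", {
  # N = 6, K = 2, n_fixed = 2, k_fixed = 1, n_extra = 2: draw 2 of the 4
  # outside genes of which 1 is a member
  outside <- c("m", "o1", "o2", "o3")
  draws <- utils::combn(outside, 2, simplify = FALSE)
  frac <- mean(vapply(draws, function(d) sum(d == "m"), numeric(1)) == 1)
  expect_equal(p_k_extra(6, 2, 2, 1, 2, 1), frac)
  expect_equal(p_k_extra(6, 2, 2, 1, 2, 1), 1 / 2)
  # no members left outside the fixed union
  expect_equal(p_k_extra(10, 3, 5, 3, 2, 0), 1)
  expect_error(p_k_extra(10, 3, 5, 4, 2, 0), "k_fixed")
})

test_that("both hypergeometric laws are normalised over their supports", {
  rint <- function(lo, hi) lo + sample.int(hi - lo + 1L, 1L) - 1L
  withr::with_seed(31, {
    for (i in 1:60) {
      N <- rint(2, 200)
      n_fixed <- rint(0, N)
      n <- rint(0, N)
      ne <- 0:min(n, N - n_fixed)
      expect_equal(sum(p_n_extra(N, n_fixed, n, ne)), 1, tolerance = 1e-12)
      K <- rint(0, N)
      k_lo <- max(0, K - (N - n_fixed)) # members must fit outside the union too
      k_fixed <- rint(k_lo, min(K, n_fixed))
      n_extra <- rint(0, N - n_fixed)
      ke <- 0:min(n_extra, K - k_fixed)
      expect_equal(sum(p_k_extra(N, K, n_fixed, k_fixed, n_extra, ke)), 1, tolerance = 1e-12)
    }
  })
})

test_that("the three evaluation modes of the conditional walk agree exactly", {
  tab <- random_score_table(60, platforms = c("x1", "x2"), seed = 8)
  members <- withr::with_seed(8, sample(tab$gene, 12))
  fixed <- rank_genes(tab, "x1")
  knots <- c(5, 10, 20, 30, 45, 60)
  w_a <- expected_conditional_walk(fixed, members, knots = knots, method = "analytic")
  w_s <- expected_conditional_walk(fixed, members, knots = knots, method = "sum")
  w_e <- expected_conditional_walk(fixed, members, knots = knots, method = "exact")
  expect_equal(w_a$value, w_s$value, tolerance = 1e-10)
  expect_equal(w_a$value, w_e$value, tolerance = 1e-10)
})

test_that("the conditional walk dominates the fixed hit count and ends at K", {
  tab <- random_score_table(150, platforms = c("x1", "x2", "x3"), seed = 12)
  members <- withr::with_seed(12, sample(tab$gene, 25))
  fixed <- lapply(c("x1", "x2"), function(f) rank_genes(tab, f))
  cond <- expected_conditional_walk(fixed, members, permuted = "x3")
  jw <- joint_walk(fixed, members)
  expect_true(all(cond$value >= jw$value - 1e-12))
  expect_true(all(diff(cond$value) >= -1e-12))
  expect_equal(cond$value[cond$rank == 150], 25)
})

test_that("conditional walks reject permuted-feature misuse", {
  tab <- random_score_table(30, platforms = c("x1", "x2"), seed = 4)
  fixed <- rank_genes(tab, "x1")
  members <- tab$gene[1:5]
  expect_error(
    expected_conditional_walk(fixed, members, permuted = "x1"),
    "among the fixed"
  )
  expect_error(
    expected_conditional_walk(fixed, members, permuted = c("x2", "x3")),
    "exactly one randomised platform"
  )
})

test_that("forcing the Monte-Carlo permutation reproduces the joint walk", {
  tab <- random_score_table(40, platforms = c("x1", "x2"), seed = 6)
  members <- withr::with_seed(6, sample(tab$gene, 8))
  fixed <- rank_genes(tab, "x1")
  other <- rank_genes(tab, "x2")
  genes <- sort(tab$gene, method = "radix")
  perm <- match(genes, other$gene) # x2's actual positions, as a "random" draw
  mc <- mc_conditional_walk(fixed, members,
    n_perm = 3, perms = cbind(perm, perm, perm)
  )
  jw <- joint_walk(list(fixed, other), members)
  expect_equal(mc$value, jw$value)
  expect_equal(max(mc$se), 0)
})

test_that("Monte-Carlo conditional walks are seed-reproducible", {
  tab <- random_score_table(50, platforms = c("x1", "x2"), seed = 3)
  members <- tab$gene[c(2, 9, 17, 33)]
  fixed <- rank_genes(tab, "x1")
  a <- mc_conditional_walk(fixed, members, n_perm = 50, seed = 99)
  b <- mc_conditional_walk(fixed, members, n_perm = 50, seed = 99)
  expect_identical(a$value, b$value)
  c2 <- mc_conditional_walk(fixed, members, n_perm = 50, seed = 100)
  expect_false(identical(a$value, c2$value))
})

test_that("analytic conditional walks agree with the Monte-Carlo oracle", {
  withr::with_seed(77, {
    for (i in 1:3) {
      N <- sample(150:250, 1)
      tab <- random_score_table(N, platforms = c("x1", "x2", "x3"), seed = 200 + i)
      members <- sample(tab$gene, sample(10:25, 1))
      n_fixed_feats <- sample(1:2, 1)
      fixed <- lapply(c("x1", "x2")[seq_len(n_fixed_feats)], function(f) rank_genes(tab, f))
      knots <- unique(round(seq(10, N, length.out = 25)))
      ana <- expected_conditional_walk(fixed, members, knots = knots)
      mc <- mc_conditional_walk(fixed, members, n_perm = 2000, knots = knots, seed = 300 + i)
      expect_true(all(abs(ana$value - mc$value) <= 3 * mc$se + 1e-9))
    }
  })
})

test_that("a pure-noise platform adds nothing beyond its conditional expectation", {
  # joint walk of fixed + noise should not positively deviate from the
  # analytic conditional walk that randomises the noise platform
  withr::with_seed(55, {
    ps <- vapply(1:4, function(i) {
      N <- 400
      tab <- random_score_table(N, platforms = c("x1", "x2"), seed = 400 + i)
      # make x1 informative so the gene set is non-trivial
      members <- tab$gene[rank(-tab$x1) <= 60]
      fixed <- rank_genes(tab, "x1")
      noise <- rank_genes(tab, "x2")
      knots <- knot_grid(N, 100)
      jw <- normalize_walk(downsample_knots(joint_walk(list(fixed, noise), members), 100))
      cond <- normalize_walk(expected_conditional_walk(fixed, members, knots = knots, permuted = "x2"))
      compare_walks(jw, cond, threshold = 1e-4)$p_value
    }, numeric(1))
    expect_true(all(ps > 1e-4))
  })
})
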