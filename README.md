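# mgsea

Multivariate gene set enrichment analysis via conditional random walks.

## The problem

Classical preranked gene set enrichment analysis (GSEA) asks whether the
top-scoring genes of **one** feature platform are over-represented in a
functional gene set. Modern studies score the same genes on several
platforms at once — copy-number variation (CNV), DNA methylation, mRNA
expression — and the interesting question is combinatorial: for a given
gene set, does each platform carry *independent* enrichment information, is
one platform's information *subsumed* by the others, or are two platforms
*redundant* (interchangeable)?

`mgsea` answers this with random walks over ranked gene lists. For a
universe of N genes and a gene set S with K members:

* the **univariate walk** y(x) counts members of S among the top-x genes of
  one platform's descending-score ranking; under an uninformative ranking it
  hugs the null line y_φ(x) = (K/N)·x;
* the **joint walk** of a platform subset counts members of S in the union
  of the subsets' top-x prefixes;
* the **conditional walk** y_{Fi|rest}(x) is the *expected* joint walk when
  platform Fi's ranking is replaced by a uniformly random permutation while
  the other rankings stay fixed. It has a closed form built from two nested
  hypergeometric laws: if the fixed prefixes cover n_fixed genes
  (k_fixed of them members), the random prefix of depth n contributes
  n_extra new genes with probability
  C(N−n_fixed, n_extra)·C(n_fixed, n−n_extra)/C(N, n), and k_extra new
  members with probability
  C(K−k_fixed, k_extra)·C(N−n_fixed−K+k_fixed, n_extra−k_extra)/C(N−n_fixed, n_extra);
  taking both expectations collapses the walk to
  y(n) = k_fixed(n) + n·(K−k_fixed(n))/N.

Normalized walks are compared by one-sided Mann-Whitney U tests over a knot
grid. Platform i is **dominant** when its univariate walk beats the null
and every joint walk containing i beats the conditional walk that
randomises i; platforms i and j are **redundant** when both are
univariately significant yet no joint walk containing both beats either of
their conditional walks (redundancy is closed transitively). For three
platforms this yields the canonical 16 comparisons per gene set.

The package also provides a kernel-density mutual-information scorer
(gene score = I(feature value; sample subtype) in nats), a permutation FDR
calibration for the significance threshold, and a simulator that plants the
four canonical combinatorial relations used throughout the test suite.

## Worked example

```r
library(mgsea)

# plant a dataset where x1 and x2 are redundant noisy copies of one signal
sim <- simulate_mgsea(model = 4, n_genes = 1000, seed = 1, center = TRUE)
fit <- mgsea(sim_score_table(sim), sim_gene_sets(sim),
             n_knots = 1000, threshold = 1e-10)
fit
#> <mgsea_result> 1 gene set(s), 3 platforms (x1, x2, x3), N = 1000, 1000 knots, threshold 1e-10
#> # A tibble: 1 × 3
#>   set         K pattern
#>   <chr>   <int> <chr>
#> 1 planted   481 none

fit$patterns$redundant[[1]]
#>      feature_a feature_b
#> [1,] "x1"      "x2"

dplyr::filter(tidy(fit), significant)[, c("comparison", "p_value")]
#> # A tibble: 8 × 2
#>   comparison             p_value
#>   <chr>                    <dbl>
#> 1 C(x1) vs null        7.31e- 77
#> 2 C(x2) vs null        2.62e- 77
#> 3 C(x1,x2) vs null     1.21e-112
#> 4 C(x1,x3) vs null     3.25e-112
#> 5 C(x2,x3) vs null     9.10e-112
#> 6 C(x1,x2,x3) vs null  2.78e-142
#> 7 C(x1,x3) vs C(x1|x3) 1.10e- 43
#> 8 C(x2,x3) vs C(x2|x3) 2.76e- 41
```

Reading: x1 and x2 are each strongly enriched against the null, and each
adds information beyond the independent noise platform x3 (rows 7–8), but
C(x1,x2) never beats C(x1|x2) or C(x2|x1): once one of the pair is in the
union, randomising the other loses nothing. Neither platform is dominant
and the pair (x1, x2) is classified redundant — exactly the planted
structure. For a gene set with a genuinely dominant platform all of its
`C(...) vs C(i|...)` comparisons turn significant and `pattern` names the
dominant set, e.g. `"x1"` for model 1.

Plotting: `autoplot(walk_curves(sim_score_table(sim), sim_gene_sets(sim)))`
overlays all joint, null and conditional curves of one gene set;
`autoplot(fit)` gives a p-value heatmap across gene sets.

A thin command-line front end covering the pipeline
(`run`, `simulate`, `mi`, `fdr`) is installed under
`system.file("scripts", "mgsea", package = "mgsea")`.

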