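---
title: "Multivariate enrichment walks: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multivariate enrichment walks: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mgsea)
```

## The model

Preranked enrichment analysis reduces one platform's evidence about a gene
set S (K genes inside a universe of N) to a cumulative hit-count walk
y(x): the number of members of S among the top-x genes when the universe is
sorted by descending feature score. An uninformative ranking places members
uniformly, so the walk's null expectation is the straight line
y(x) = (K/N)·x. `mgsea` extends this picture to m platforms:

* the joint walk of a platform subset counts members in the **union** of
  the subsets' top-x prefixes. Because a union can only grow, the joint
  walk dominates each single-platform walk pointwise, so comparing it
  against single-platform walks directly says nothing about added
  information;
* the fair baseline is the **conditional walk**: the expected joint walk
  when one platform's ranking is replaced by a uniformly random
  permutation while the others stay fixed. If the fixed prefixes cover
  n_fixed distinct genes, k_fixed of them members, the random prefix of
  depth n contributes n_extra new genes with hypergeometric probability
  C(N−n_fixed, n_extra)·C(n_fixed, n−n_extra)/C(N, n), and, given n_extra,
  k_extra of them are members with probability
  C(K−k_fixed, k_extra)·C(N−n_fixed−K+k_fixed, n_extra−k_extra)/C(N−n_fixed, n_extra).

The conditional walk is the double expectation over these two laws. Both
inner sums are hypergeometric means, so the whole expression collapses to
the closed form

y(n) = k_fixed(n) + n·(K − k_fixed(n))/N.

`expected_conditional_walk()` evaluates this closed form by default;
`method = "sum"` (explicit outer sum) and `method = "exact"` (explicit
double sum) are retained because the test suite verifies all three agree
to 1e-10 and the exact mode documents the derivation. A Monte-Carlo
estimator (`mc_conditional_walk()`) serves as an independent oracle: the
suite checks agreement within three Monte-Carlo standard errors at every
knot over randomly drawn instances.

Only one platform may be randomised at a time. The union of two or more
permuted prefixes has inclusion-exclusion structure with no comparably
simple law, so such conditionals are rejected with an error rather than
approximated.

## Comparisons and classification

Normalized walks (values divided by K, so curves read as CDFs over ranks)
are compared by a one-sided Mann-Whitney U test on their values over a
shared knot grid, alternative "curve A stochastically larger than curve B".
The field's convention of treating the curves as CDFs leaves the sample
construction open; knot-value sampling is the one construction that applies
uniformly to empirical (step) and expected (smooth) curves, so it is used
throughout. An alternative — sampling the member hit ranks themselves — is
noted as possible but not implemented. Consequences of the knot-value
choice worth knowing:

* p-values depend on the knot count: more knots mean more (correlated)
  samples and stronger extremes. Thresholds are therefore meaningful only
  relative to a fixed grid, which is why `permutation_fdr()` calibrates the
  threshold empirically rather than trusting nominal uniformity;
* identical curves give p = 0.5 (never significant), and a curve strictly
  below its baseline gives p near 1 — one-sidedness is essential because a
  conditional walk always lies on or above the fixed-union hit count.

The normal approximation with tie and continuity correction is used for the
U statistic; for fewer than 30 tie-free knots the exact distribution is
used instead. A degenerate all-tied comparison (zero variance) is defined
as p = 0.5. `stats::wilcox.test` is not used as the backend because its
normal approximation returns NaN for fully tied curves, but it serves as
the independent cross-check in the unit tests.

For m platforms, `enumerate_comparisons()` emits every nonempty subset's
walk against the null line plus, for each subset of size ≥ 2 and each
member i, the subset walk against the conditional walk randomising i:
16 comparisons for m = 3, and 2^m − 1 + Σ_{t≥2} C(m,t)·t in general
(43 for m = 4). Classification then applies two rules:

* platform i is **dominant** if C(i) beats the null and C(T ∪ {i}) beats
  C(i | T) for every non-empty context T not containing i (the empty
  context being the univariate-vs-null condition);
* platforms i, j are **redundant** if both are univariately significant
  and no C(T ∪ {i,j}) beats C(i | ...) or C(j | ...) in any context.
  Redundancy is transitively closed over the pair graph.

Dominance is anti-monotone in the threshold (lowering it never adds
dominant platforms), and a platform duplicated byte-for-byte can never be
dominant against its copy because its conditional walk dominates the joint
walk pointwise; both properties are exercised in the test suite.

### The joint-versus-null baseline

The union of m uniformly random prefixes of size x covers
K·(1 − ((N−x)/N)^m) members in expectation — strictly above the straight
line for m ≥ 2. The straight line is nevertheless the default baseline for
joint-versus-null comparisons, matching the convention this analysis family
reports; it makes those comparisons slightly anti-conservative. The
bias-corrected baseline is available as `corrected_null = TRUE`
(`null_joint_walk()`), off by default. Classification is largely
insulated from this bias because dominance and redundancy hinge on the
joint-versus-conditional comparisons, which use the exact conditional law.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `n_knots` | 500 | ranks at which walks are evaluated (`round(i·N/n_knots)`, always including N); values between knots are linear interpolations. 500 reflects ten-fold down-sampling of a 5000-gene universe; for N ≤ 1000 the package's own studies use full resolution (`n_knots = N`) since nothing needs to be saved |
| `threshold` | 1e-10 | Mann-Whitney p-value at or below which a comparison is significant; calibrate with `permutation_fdr()` for your universe/knot configuration |
| `min_size` | 50 (`restrict_gene_sets`), 1 (`mgsea`) | post-intersection gene set size floor; K for all walks is the post-intersection size |
| `scale` | 20 | logistic steepness of the simulator |
| `noise_sd` | 0.1 | standard deviation of the model-4 noise; read as σ = 0.1 (not σ² = 0.1) because larger noise visibly weakens the planted redundancy the model exists to show |
| `bw` | `"nrd0"` | KDE bandwidth rule for mutual information; `"SJ"` available |

Ranks are 1-based and "top x" includes rank x. Score ties are broken by
ascending gene identifier (radix order, locale-independent); genes missing
a platform's score rank last rather than being dropped so every platform's
list has the same length N, which the union construction requires.

## Mutual-information scores

For labelled samples (e.g. tumour subtypes), the per-gene, per-platform
score is the mutual information between the continuous feature value and
the categorical label,

I(X;Y) = Σ_i P(y=i) ∫ p(x|y=i) log( p(x|y=i) / p(x) ) dx,

in nats (only relative ranking matters downstream, so the log base is a
free choice). Class-conditional densities are Gaussian KDEs with
Silverman's-rule bandwidth; P(y) is the empirical class fraction; the
integral is a trapezoid rule on an equally spaced grid spanning the
observed range plus 10% padding each side (the integral's limits are
otherwise unspecified; padding 0.1 and 512 grid points put the grid error
well below sampling noise). Samples missing the feature value are excluded
pairwise — from both the densities and the class fractions of that gene —
rather than deleting the sample globally, because sporadic missingness is
the norm in multi-platform data.

Two deliberate choices:

* the **marginal** p(x) is the class-fraction-weighted mixture of the
  class-conditional KDEs, not an independently bandwidthed KDE of the
  pooled sample. With well-separated classes an independent marginal
  bandwidth is much wider than the class bandwidths and the plug-in
  estimate inflates past the H(Y) ceiling; the mixture construction keeps
  the estimator consistent and recovers H(Y) = ln 2 exactly for a
  perfectly separating binary feature;
* a class with zero spread falls back to a kernel of 1% of the pooled
  standard deviation. `stats::bw.nrd0`'s own zero-variance fallback is on
  the unit scale and would smear point masses into heavy overlap.

Known bias: Silverman bandwidths smooth across sharp class boundaries, so
a feature deterministically binned into contiguous classes is estimated a
few percent below H(Y) at n = 5000; the Sheather-Jones rule (`bw = "SJ"`)
roughly halves that boundary bias and is what the corresponding property
test uses. Estimates are clipped at zero; a constant feature scores
exactly 0.

Preprocessing helpers mirror standard multi-platform practice: per-gene
rank-to-CDF transformation with tie-averaged ranks (`rank_to_cdf()`),
probe-to-gene averaging over non-missing probes (`aggregate_probes()`),
removal of genes with a majority of missing-or-zero values
(`filter_invalid_genes()`), and a universe built from the union of
top-ranking genes across platforms cut to an exact target size
(`build_universe()`). Copy-number pipelines sometimes post-adjust CDF
values to damp amplification/deletion over-estimation; no formula for such
an adjustment is defined here, so `rank_to_cdf()` output is used as-is and
any adjustment is left to the caller as a plain column transformation
before ranking.

## The simulator and the recovery study

`simulate_mgsea()` draws 1000 uniform scores per platform and memberships
from the logistic models described in its help page; it is the package's
test substrate and defines the study conditions.

The plain logistic forms saturate: with `P(member) = σ(20·x1)` the mean
membership fraction is ∫₀¹σ(20u)du ≈ 0.965, so about 96% of the universe
is in the gene set, the normalized walk can sit at most a few percent above
the diagonal, and no comparison can reach a stringent significance level —
the planted dominance is real but statistically invisible at N = 1000. The
`center` option replaces the linear predictor with
σ(scale·(Σxᵢ − m/2)) (for model 4, σ(scale·(z − ½))), balancing membership
near 50% and making the planted relations detectable. The package's
recovery studies therefore run the simulator with `center = TRUE`;
`center = FALSE` remains the default so the plain forms are what a caller
gets unless they opt in.

The recovery protocol (test suite and `scripts/acceptance.R`):
n = 1000 genes, scale 20, noise σ = 0.1, walks at full resolution
(`n_knots = N` — down-sampling exists to save time on 5000-gene universes
and is unnecessary at this size; at 100 knots the Mann-Whitney samples are
too small to resolve the conditional deviations of models 2–3 at any
threshold), threshold 1e-10, ten seeds per model. Expected outcomes:
model 1 → dominant set exactly {x1}; model 2 → {x1, x2}; model 3 →
{x1, x2, x3}; model 4 → x3 not dominant and (x1, x2) redundant; each in at
least 8 of 10 seeds. The threshold is vetted against the null: across 40
datasets with memberships i.i.d. Bernoulli(½) independent of all scores
(`simulate_generic(beta = c(0, 0, 0))`), no platform may be classified
dominant. Membership vectors that come out all-member or all-non-member
are redrawn so K is always valid; the redraw is reported via a message.

What the simulator does **not** emulate: real platform marginals (CNV
segment structure, methylation β-value bimodality, expression dispersion),
inter-gene correlation, probe-level noise, or missingness. Passing the
recovery study shows the walk/conditional/classification machinery
recovers planted combinatorial structure under clean uniform scores; it
does not certify behaviour under real multi-omic noise, where the FDR
calibration below is the intended guard.

## Permutation FDR

`permutation_fdr()` permutes the gene-to-score assignment (memberships
fixed), one shared permutation per trial across all gene sets — the
cheapest reading consistent with permuting the scores of the genes — and
reports min(total permuted hits / (empirical hits × trials), 1) per
threshold. When no empirical set passes a threshold the ratio is
undefined and reported as 1 (conservative). On pure-noise scores with 200
sets the curve sits near 1 everywhere (numerator and denominator share the
null law); a planted top-concentrated set drives the strict-threshold FDR
to 0. Both behaviours are computed in the acceptance checks. The default
1000 trials matches full-scale calibration practice; the test suite uses
50.

## Numerical notes

* Both hypergeometric laws are evaluated in log space via `lchoose`;
  impossible combinations contribute probability 0. Arguments describing
  impossible geometry (more members than genes outside the fixed union)
  are rejected — R's `choose` would otherwise silently apply the
  generalised binomial for negative upper arguments.
* Walk construction is O(m·N) per gene set via each gene's first-entry
  rank across the m rankings (a running `pmin`), so a full three-platform
  analysis of one gene set at N = 1000 costs milliseconds.
* All stochastic functions take an explicit `seed` and restore the RNG
  state (`withr::with_seed`); fixed seed means bitwise-identical output.

## Limitations

* Weighted enrichment statistics (the weighted Kolmogorov-Smirnov family)
  and leading-edge gene extraction are out of scope; the walk is the plain
  hit count.
* Conditional walks with several simultaneously randomised platforms are
  not supported (no closed form; see above).
* The Mann-Whitney samples are autocorrelated curve values, so nominal
  p-values are not calibrated in the frequentist sense; use
  `permutation_fdr()` to choose thresholds.
* Gene identifier matching is exact and case-sensitive by default
  (`ignore_case = TRUE` available); no identifier normalisation or
  ontology-aware reduction of gene set collections is attempted.
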