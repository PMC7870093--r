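---
title: "Distance distributions for nearest-neighbor feature selection: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance distributions for nearest-neighbor feature selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neighbordist)
```

## Why distance distributions

Relief-based algorithms and projected-distance regression score attributes by
contrasting one-dimensional distance projections ("diffs") between neighbors.
Their behaviour therefore hinges on the pairwise distance distribution: how
large a typical distance is, how dispersed distances are, and how many
instances fall inside a neighborhood radius. `neighbordist` implements the
asymptotic theory of those distributions on *null* data — independent
instances, independent attributes, no effects — for the metrics used in
practice, together with generators for exactly those null models, a
simulation harness to confront theory with samples, and the neighborhood
sizing rules the theory implies.

## The model

For an `m x p` data matrix with iid entries, the L_q distance between two
instances is `D_ij = (sum_a |X_ia - X_ja|^q)^(1/q)`. The per-attribute power
`Z = |X_ia - X_ja|^q` has a closed-form distribution for standard normal data
(generalized gamma) and standard uniform data (Kumaraswamy);
`projection_moments()` returns its mean `mu_z` and variance `sigma2_z`, and
`projection_density_numeric()` evaluates the same construction by quadrature
for any user density. The sum over `p` attributes is asymptotically normal by
the central limit theorem, and the delta method applied to `z^(1/q)` yields

* mean `(mu_z p)^(1/q)`,
* variance `sigma2_z p / (q^2 (mu_z p)^(2(1 - 1/q)))`.

Two consequences worth knowing by heart: Manhattan distances on standard
normal data have mean `2p/sqrt(pi)` and variance `2(pi - 2)p/pi` (dispersion
grows with dimension), while Euclidean distances have variance exactly 1
regardless of `p` — a distance-concentration statement. For `q = 2` the
second raw moment is also available, which gives the improved mean
`sqrt(2p - 1)` (normal) and `sqrt(p/6 - 7/120)` (uniform). The improved mean
is the package default because it is accurate at both small and large `p`;
`improved = FALSE` recovers the plain first-order estimate.

## Range (max-min) normalization and extreme values

Relief divides each diff by the attribute range `max(a) - min(a)`, so the
moments of the normalized distance involve the sample extremes of `m` draws.
`extreme_distributions()` and `extreme_moments_numeric()` implement the exact
cdf/pdf and quadrature moments for any data model. For uniform data the
closed forms `E[max] = m/(m+1)`, `E[min] = 1/(m+1)` and
`E[(max-min)^2] = (m^3 - m + 2)/((m+2)(m+1)^2)` are used directly (the last
embeds the uncorrelated-extremes approximation exactly as stated, which is
why `m >= 2` is required; at `m = 2` the exact value differs). For normal
data the maximum is asymptotically Gumbel; `normal_max_stats()` exposes the
Gumbel mean, the median and the variance `pi^2/(12 log m)`. The package uses
the **median** of the sample maximum as the point estimate when normalizing,
because the Gumbel mean systematically overestimates the observed maximum at
practical sample sizes; the mean remains available. `maxmin_lq_moments()`
assembles the normalized-distance moments; in uniform data they converge to
the standard L_q moments as `m` grows, and for normalized Euclidean on
uniform data the variance tends to `7/120`.

## GWAS metrics

Genotypes are modelled as binomial minor-allele counts `X ~ B(2, f_a)` with
per-locus MAFs drawn `U(l, u)`. Three diffs are covered: genotype mismatch
(GM), allele mismatch (AM), and the transition/transversion-weighted TiTv
diff, whose value depends on whether the locus substitutes by transition
(PuPu or PyPy encoding) or transversion (PuPy). The encoding model ties the
label probabilities to the Ti/Tv ratio `eta`: `gamma1 = 1/(eta + 1)` and
`gamma0 + gamma2 = eta/(eta + 1)`; the split between PuPu and PyPy is
arbitrary and — as every closed form depends only on `gamma1` and
`gamma0 + gamma2` — irrelevant to the theory, so `encoding_gammas()` draws it
uniformly inside a margin `epsilon`. Exact per-locus pmfs
(`gwas_diff_pmf()`), their moments, and the distance moments (sums across
independent loci) are all closed form, and the test suite checks every one
against exhaustive enumeration over the 3 x 3 genotype-pair table. The
predicted mean TiTv distance as a function of average MAF
(`titv_mean_curve()`) peaks at 0.5 — the point at which minor and common
alleles are equally frequent — and decreases with `eta`, because
transversions carry larger weights than transitions.

## Correlation-stack (rs-fMRI) metric

For time-series correlation data each subject contributes a `p x p`
correlation matrix between regions of interest. After Fisher r-to-z
transformation the off-diagonal entries are arranged in a `p(p-1) x m`
stack — ROI `a` owns rows `(a-1)(p-1)+1 .. a(p-1)` and each unordered ROI
pair appears twice per column — and columns are standardized to zero mean
and unit variance, making entries approximately standard normal. The ROI
diff sums an ROI's block of absolute differences and the distance sums all
blocks, which equals the Manhattan distance between stack columns.

The mean `2p(p-1)/sqrt(pi)` follows by linearity. The variance does not:
blocks share ROIs and pairs repeat, so treating rows as independent
(`2(pi-2)p(p-1)/pi`) underestimates the sample variance. The corrected
variance `9p(pi-2)(p-1)/(4pi)` adds a cross-covariance term equal to one
eighth of the naive variance. `fit_variance_correction()` re-estimates that
term empirically: it simulates null stacks over a grid of ROI counts,
subtracts the independence variance from each sample variance, and fits
`beta1 p^2 + beta0 p` without intercept. With the default generator the
fitted `beta1` lands near 0.08, a little below the algebraic
`(pi - 2)/(4 pi) = 0.0908`; the package reproduces this gap rather than
explaining it, and the fitted `beta0` is small and noisy because `p` and
`p^2` are nearly collinear over practical grids — only the quadratic
coefficient is a stable summary.

Two choices here were genuinely open:

* **The null-stack generator.** Nothing pins down what "random" stack data
  should be, so the package builds each subject from `p` independent
  Gaussian time series of length `T = 4p` (long enough that Fisher-z
  correlations are nearly normal, short enough to stay cheap), correlates,
  transforms and standardizes. The per-column standardization matters: it
  is what keeps the sample variance of distances near the corrected formula
  instead of the much larger value a raw duplicated stack would give.
* **The extreme-value sample size for range normalization.** An ROI block
  holds `m(p-1)` values, so `fmri_maxmin_moments()` takes the sample maximum
  over `m(p-1)` draws, as the normalized-metric formulas require.

For the ROI diff itself the linear variance `2(pi-2)(p-1)/pi` is the default
(within one block the cross-covariances are negligible); the
covariance-scaled alternative is available via `corrected = TRUE`.

## Synthetic data and what it does and does not show

All generators are deterministic under `(seed, parameters)` and default to
the study conditions of the theory: iid N(0,1) or U(0,1) matrices; binomial
genotypes with `f_a ~ U(0.05, 0.5)` and `eta = 2` (the human-typical Ti/Tv
ratio); null correlation stacks as above. Correlated variants multiply iid
normal data by the Cholesky factor of a random-graph correlation target
(`hi` on edges, `lo` off, eigenvalue-clipped to positive definiteness and
rescaled to unit diagonal), and genotypes inherit correlation through the
normal-cdf / binomial-quantile map. The correlation dial is summarized by
the average absolute pairwise correlation `mean_abs_correlation()`.

Passing tests on these generators show that the closed forms describe their
own null models, and that correlation inflates variance and skews distances
in the expected direction. They do not show that real data are null:
expression, GWAS and connectivity data carry effects, dependence and batch
structure the theory deliberately omits. The practical reading is the one
the normality screens support — distances on standardized real data are
often approximately Gaussian, so the moments are useful anchors for
neighborhood sizing, not guarantees.

The feature-selection benchmark plants `n_functional` signal attributes in
iid noise: main effects as a 0.8-SD group mean shift, interactions as
within-case pairwise correlation 0.6 with no marginal shift (a
differential-correlation surrogate for network-based epistasis simulators —
it reproduces the signature Relief must detect without modelling a specific
interaction graph). Those two magnitudes were chosen once as a moderate,
realistic signal level; they are deliberately not tuned.

## Neighborhood sizing

MultiSURF gives instance `i` the radius `R_i = mean_j D_ij - alpha sd_j
D_ij` with `alpha = 0.5`. Under a normal distance distribution the expected
number of neighbors inside such a radius is `(m-1) q_alpha`. The printed
form of `q_alpha` in the source material is ambiguous (a plain reading gives
`Phi(-0.5) = 0.309`, which contradicts the printed evaluation
`floor(0.154 (m-1)) = 15` at `m = 100`); the package defines
`q_alpha = pnorm(-2 alpha)`, the closed form that matches the printed
evaluation exactly (`q_1/2 = 0.1587`) and satisfies `q_0 = 1/2`. Simulated
MultiSURF neighborhoods on null data do in fact average `(m-1) Phi(-alpha)`
(about 31 at `m = 100`), twice the informed-k value, and the test suite
asserts that empirical size; the factor-of-two question between the two
conventions is left open here rather than silently resolved, and
`informed_k()` keeps the published evaluation. `rule_of_thumb_k()` implements `floor(m/6)`, one neighbor above
the informed value at `m = 100`. `relief_scores()` is a minimal Relief
demonstration: neighbors from unnormalized Manhattan distance,
range-normalized diffs for scoring (the Relief convention), misses minus
hits averaged over all (instance, neighbor) pairs.

## Numerical choices, degenerate inputs, limitations

* Quadratures use `stats::integrate()` with absolute tolerance `1e-10`;
  gamma functions are evaluated via `lgamma()` to avoid overflow at large
  `q`.
* A zero-range attribute (or ROI block) under normalization errors by
  default; `degenerate = "drop"` removes it with a warning. The theory never
  meets this case; real data can.
* Fisher z of |r| = 1 is clamped at 12 (only degenerate inputs reach it).
* Neighbor ties at equal distance break by ascending index, making all
  neighborhood outputs deterministic.
* Distance matrices are dense `m x m`; the package targets `m` up to a few
  thousand and makes no attempt at metric trees or sparsity.
* Shapiro-Wilk caps its sample size, so `normality_report()` subsamples to
  5000 distances under a fixed seed.
* Simulation scales in the test suite and validation harness (for example
  Manhattan-on-normal grids at `p` up to 5000 with 20 replicates, and the
  variance-correction grid `p = 20..100` with `m = 100`) are the package's
  chosen study sizes: large enough for the asymptotics to bind, small
  enough to run routinely.
* Not covered by design: missing genotypes and VCF/PLINK parsing, voxel-level
  imaging preprocessing, linkage disequilibrium, population structure, full
  projected-distance regression inference, and non-integer `q`.

## A worked check

```{r worked}
# Euclidean distances on normal data concentrate: variance near 1
X <- gen_continuous(100, 2000, "normal", seed = 1)
var(pairwise_values(lq_distance_matrix(X, q = 2)))

# theory for the same setting
lq_distance_moments(2000, 2, "normal")

# informed neighborhood size at MultiSURF's alpha
informed_k(100, 0.5)
```
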