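---
title: "Estimating and comparing partial-correlation networks from mixed psychometric measures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating and comparing partial-correlation networks from mixed psychometric measures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixedggm)
```

## The model

`mixedggm` estimates a Gaussian graphical model (GGM) over a set of
psychometric subscale scores and compares the resulting networks between two
groups.  In a GGM the variables are nodes and an edge between nodes $i$ and
$j$ carries the partial correlation

$$w_{ij} = -\frac{K_{ij}}{\sqrt{K_{ii}K_{jj}}},$$

where $K = \Sigma^{-1}$ is the precision (inverse covariance) matrix.  A
zero entry of $K$ means conditional independence given all other variables,
so the sparsity pattern of $K$ *is* the network structure.

Because subscale scores are a mix of near-continuous sums and coarse ordinal
scales, the input correlation matrix is assembled pairwise: Pearson for two
continuous variables, polyserial for a continuous–ordinal pair, polychoric
for two ordinal variables.  The polychoric/polyserial estimators assume each
ordinal score is a thresholded latent standard-normal variable; the same
latent-threshold model drives the synthetic-data generator, so the generator
and the estimator agree about what an ordinal score is.

The precision matrix is estimated by the graphical LASSO: maximize

$$\log\det K - \operatorname{tr}(SK) - \lambda \sum_{i \ne j} |K_{ij}|,$$

with the penalty on off-diagonal entries only (marginal scales are left
untouched).  The penalty $\lambda$ is chosen by BIC,
$-2\ell + E\log n$ with $E$ the number of active edges, over a log-spaced
grid of 100 values from $\lambda_{\max}$ (the largest off-diagonal $|S_{ij}|$,
where the network is empty) down to $0.01\,\lambda_{\max}$, with warm starts;
BIC ties resolve to the sparser model.

How the likelihood in that BIC is evaluated matters more than it looks.
Scoring the penalized estimate itself — the convention of much network
psychometrics tooling — systematically favors dense models: at large
$\lambda$ the active edges are strongly biased toward zero, so their poor
likelihood drags the score down and the minimum shifts toward small
$\lambda$, where spurious edges ride along.  In simulation (6 nodes, 4 true
edges at partial correlation 0.4, $n = 2000$) that convention returned 1–4
spurious extra edges in 19 of 20 replicates.  `select_penalty()` therefore
treats the lasso path as a model-search device: each candidate support is
re-estimated by support-constrained unpenalized maximum likelihood and BIC
is evaluated at that refit — the classical definition of BIC — which
recovers the exact support in 20 of 20 of the same replicates.  The
returned network carries the refit (unshrunken) partial correlations.
`refit = FALSE` restores the penalized-scoring convention; it remains
useful when the goal is to mimic analyses performed with that tooling,
whose characteristically dense, heavily shrunken networks (e.g. a
control group whose many weak conditional dependencies all survive with
small weights) the refit convention will legitimately refuse to select at
small $n$.

## Stage order: why the significance filter acts on edges

Practice in this literature retains only significant correlations.  Two
compositions are possible: zero out non-significant entries of $S$ *before*
the graphical LASSO, or estimate first and then remove edges whose
underlying correlation is not significant.  We ship the second, after
measuring the first: zeroing a third of the entries of a smooth polychoric
matrix produces an $S$ that is close to no sparse-precision model at all.
Its repaired version is often near-singular, the Gaussian likelihood then
rewards the dense inverse, and BIC selection collapses to the bottom of the
penalty grid — at $n \approx 80$ this produced pathological networks
(partial correlations of 0.8 from independent data) in roughly a third of
simulated samples.  Filtering the *estimated* edges keeps the likelihood
geometry intact and leaves $\lambda^\ast$ stable; `significance_filter()`
still exposes the matrix-level operation for users who want the other
composition explicitly.

The filter tests each correlation at unadjusted $\alpha = 0.05$.  For the
polychoric and polyserial coefficients the p-value is a likelihood-ratio
test against independence with thresholds held fixed.  We measured the Wald
alternative (numerically differentiated observed information at
$\hat\rho$) as anticonservative at these sample sizes — 6.7% rejections at
nominal 5% with $n = 76$ — while the LR test sits at 5.4%; with eleven
nodes, per-pair miscalibration compounds quickly, so the LR test is the
default and only recipe.

Polychoric matrices assembled pairwise need not be positive semidefinite.
`nearest_psd()` clips eigenvalues at $10^{-8}$, reconstructs, and rescales
the diagonal to 1; it is a no-op on PSD inputs.  Ordinal variables with more
than 10 observed levels are treated as continuous — their contingency
tables are too sparse for the polychoric likelihood to be worth its cost.

## Centrality conventions

Three indices are computed per node, following their standard weighted
definitions: strength $k_i = \sum_j |w_{ij}|$; betweenness
$b_i = \sum_{j<k} p_{jk}(i)/p_{jk}$ over weighted geodesics with fractional
credit for ties, endpoints excluded, unnormalized; closeness as the
reciprocal average geodesic distance $(n-1)/\sum_j d_{ij}$, restricted to
the node's connected component, 0 for isolated nodes.  Distances are
$d_{ij} = 1/|w_{ij}|$ — the standard transform for partial-correlation
networks, making stronger edges shorter.  Absolute values are used for
strength and distances because these networks contain negative edges and
centrality should not cancel across signs; `signed = TRUE` and the
unscaled closeness variant `1/\sum d` are available where a different
convention is needed.  Geodesic ties are detected with a relative tolerance
of $10^{-9}$; all tied geodesics are counted.

## Community detection

Communities are found by Louvain-style greedy modularity optimization on
absolute edge weights:

$$Q = \frac{1}{2m}\sum_{ij}\left(a_{ij} - \frac{s_i s_j}{2m}\right)
\delta(c_i, c_j).$$

A single Louvain run depends on the node sweep order, so `louvain()` runs
20 seeded restarts with shuffled orders and keeps the best $Q$; local moves
take the largest strictly positive gain with ties to the lowest community
index, and levels aggregate until no move helps.  The resolution parameter
is fixed at 1.  $Q < 0.3$ is read as no community structure, $0.3$–$0.7$ as
genuine community structure, above $0.7$ as exceptionally strong — with
$Q \approx 0$ meaning the division is no better than random.

## The synthetic two-group design

The generator (`asd_td_specs()`) emulates a two-group study of 11
social-cognition subscales: four eye-gaze emotion-recognition composites
(integer 0–14), three comic-strip theory-of-mind subscales (integer 0–5),
and four social-information-processing steps (encoding 0–4, interpretation
0–4, response construction 0–8, response evaluation continuous 0–36), for
$n = 81$ typically-developing-like and $n = 76$ ASD-like subjects.

Each group is a latent Gaussian with a structured precision matrix,
rescaled to correlation form so thresholds are standard-normal quantiles.
The TD-like model is a single dense component: every pair has partial
correlation 0.08, chosen against the positive-definiteness bound
$1/(p-1) = 0.1$ for an equi-partial-correlation model — the largest
"moderate uniform" value the geometry allows.  The ASD-like model has three
blocks: the six perception/interpretation measures, the four
reasoning/response measures, and the encoding node exactly isolated (its
precision row is zero).  Within-block partial correlations are 0.3; a block
cannot be equicorrelated at 0.3 and stay positive definite, so each block
is the densest 3-regular structure it admits (a prism and a complete
graph), keeping the minimum eigenvalue at 0.1 before the two weak 0.1
bridges that connect the blocks.  Ordinal thresholds are placed by quantile
so the simulated marginals reproduce the skewed, ceiling-heavy score
distributions typical of these instruments (e.g. emotion-subscale medians
of 4–5 on a 0–5 scale), with group-specific locations.

What the generator does *not* emulate: item-level response processes,
missing data, floor/ceiling measurement artifacts beyond what thresholding
produces, or any non-Gaussian latent dependence.  Tests passing on this
design show the pipeline recovers the structure its own model class
generates — they cannot certify behavior on real data whose latent
structure violates the GGM or the latent-normal link.

## The bootstrap comparison and its two z conventions

Each group's network is nonparametrically bootstrapped (subjects resampled
with replacement; default $B = 1000$), re-running the entire estimation
chain per replicate and collecting the three centrality indices per node.
Replicates where a resampled column is constant or estimation fails are
redrawn and counted, so exactly $B$ replicates are always retained.

`centrality_z_test()` then compares groups per node and metric.  Its
default denominator combines the two bootstrap SDs in quadrature,
$z = (\bar\theta_a - \bar\theta_b)/\sqrt{s_a^2 + s_b^2}$: the bootstrap SD
estimates each group's sampling SD, so this is the usual calibrated
two-sample construction, and in simulations with identical generating
networks its Bonferroni family-wise error stays at or below the nominal
5%.  The `"se"` variant divides instead by
$\sqrt{s_a^2/B_a + s_b^2/B_b}$ — the arithmetic behind some published
bootstrap z tables.  Its denominator shrinks with the number of bootstrap
replicates rather than with the information in the sample, inflating $|z|$
by roughly $\sqrt{B}$; under the null it rejects almost every family.  It
is provided for comparability with such tables, not for inference.  The
flip side of using the calibrated test is power: at these sample sizes the
sampling SD of a node's centrality is large relative to realistic group
differences, so after Bonferroni correction over $11 \times 3$ comparisons
(requiring $|z| > 3.19$), even the most affected node — encoding, with a
true strength difference equal to the TD node's entire strength — rarely
clears the bar.  Single-node centrality differences at $n \approx 80$ are
simply hard to certify with a calibrated test; the acceptance suite records
this honestly rather than substituting the anticalibrated variant.

Bonferroni uses $m$ = the number of testable cells (cells whose denominator
is zero are reported `NA` and excluded).  Descriptive score comparisons use
the pooled-variance Student t for continuous measures (Welch behind a
flag) and Mann–Whitney for ordinal ones, Bonferroni-corrected across
measures.

## Numerical choices

* Graphical lasso: block coordinate descent, convergence when the maximum
  $W$ change per sweep drops below $10^{-5}$ times the mean absolute
  off-diagonal of $S$, 1000-sweep cap; exact zeros come from the
  soft-threshold, not rounding.  KKT residuals are checked in the test
  suite at $10^{-4}$.
* Polychoric/polyserial: two-step ML (thresholds from marginals, then
  one-dimensional Brent search on $[-0.999, 0.999]$, x-tolerance
  $10^{-7}$); bivariate-normal rectangle probabilities via Gauss–Legendre
  quadrature accurate to ~$10^{-15}$; cell probabilities floored at
  $10^{-14}$.  Estimates at the clipping boundary (e.g. a perfectly
  diagonal table) are reported with `clipped = TRUE`.
* Degenerate inputs: constant columns error with the column named;
  edgeless networks error on `modularity()`/`louvain()` (Q undefined) and
  yield all-zero centralities; tiny samples run end to end and simply
  return empty or near-empty networks.
* All randomness flows from explicit seeds (one root seed in
  `run_pipeline()`, per-stage children derived from it); rerunning a
  config reproduces every artifact byte for byte, and generator calls
  restore the caller's RNG state.

## Problem sizes in the validation suite

The test suite exercises: oracle equivalence of betweenness/closeness
against exhaustive simple-path enumeration on 100 random graphs of up to 8
nodes; exhaustive-partition modularity optima on another 100; structure
recovery on a 6-node chain at $n = 2000$ over 20 replicates; polychoric
recovery at $n = 10{,}000$ across latent $\rho \in \{-0.6, \dots, 0.6\}$;
the two-group modularity contrast over 20 simulated studies; and
calibration of the bootstrap comparison over 50 null experiments at
$B = 200$ (a deliberate scale-down of the default $B = 1000$ that leaves
the SD estimates adequate while keeping the suite fast).

## Known limitations

* The GGM treats polychoric correlations as if they were Pearson
  correlations from $n$ Gaussian observations; their extra sampling noise
  is not propagated into BIC, which can make selection slightly denser
  than ideal at small $n$.
* Modularity on absolute weights discards edge signs; signed-modularity
  variants are out of scope.
* The bootstrap comparison tests node-by-node differences; it is not a
  global network-invariance test.
* Closeness conventions differ across the literature; both the
  $(n-1)/\sum d$ and $1/\sum d$ forms are implemented, and reported values
  are only comparable under a fixed choice.

## A worked run

```{r, eval = FALSE}
cfg <- pipeline_config(B = 200, seed = 11)
report <- run_pipeline(cfg)
report
report$groups$ASD$communities
subset(as.data.frame(report$comparison), significant)
```
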