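---
title: "Cell-state deconvolution along single-cell trajectories: model and methods"
author: "CARDecon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-state deconvolution: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CARDecon)
```

# The problem

Bulk RNA-seq measures a mixture of cells. Classical deconvolution recovers
the proportions of discrete cell *types*; CARDecon targets the finer
question of how cells of one focal type are distributed along a continuous
one-dimensional *state* trajectory (differentiation, activation,
keratinization, ...). The trajectory itself — a per-cell pseudotime for the
focal type — is an input, taken from any trajectory-inference tool applied
to a reference scRNA-seq dataset; CARDecon does not infer trajectories.

# The model

The focal-type cells of the reference are ranked by pseudotime and split
into $m$ consecutive states (equal-count bins of the ranking, robust to
non-uniform pseudotime density). For a bulk sample, let $y$ be the
expression of $n$ signature genes. With the $i$-th state as the focal
state,

$$y = x_i \beta_i + C\gamma + Z\alpha + e, \qquad e \sim N(0, I\sigma_e^2)$$

where $x_i$ is the mean signature profile of the cells in state $i$
($\beta_i$ the abundance of that state, the quantity of interest), $C$
holds the mean profile of every *other* cell type (fixed covariates), and
$Z$ holds every focal-type cell individually. Because there are usually
more cells than genes, $\alpha$ is a random effect. Abundances of cells at
nearby states are correlated, so $\alpha$ gets a conditional-autoregressive
(CAR) structure over trajectory distance: with weights
$w_{ij} = \exp(-d_{ij}^2)$, $W = \{w_{ij}\}$ symmetric with zero diagonal
and $D$ the diagonal of row sums,

$$\operatorname{var}(\alpha) = (D - \theta W)^{-1}\lambda^2,$$

which is symmetric positive definite for $\theta \in [0, 1)$ (we restrict
$\theta$ to this range: negative trajectory autocorrelation has no
biological reading, and positive definiteness is guaranteed by diagonal
dominance). The marginal covariance of $y$ is
$V = Z(D - \theta W)^{-1}\lambda^2 Z' + I\sigma_e^2$.

## Distance scale (bandwidth)

$\exp(-d^2)$ is scale-sensitive and pseudotime units are arbitrary, so the
package min–max rescales pseudotime to $[0,1]$ and multiplies distances by
a bandwidth $h$. The default (`bandwidth = "auto"`) sets
$h = \sqrt{\ln 2} / \operatorname{median}(d_{ij})$, which calibrates the
median pairwise weight to exactly $0.5$ — a neutral middle ground between
an effectively diagonal covariance ($h$ large) and an exchangeable one
($h$ small). Any positive number can be supplied instead.

## Estimation and the computational shortcut

$(\theta, \lambda^2, \sigma_e^2)$ are estimated by REML under the *null*
model that drops the focal fixed effect and keeps all focal cells in $Z$
— once per sample, not once per state. The fitted $\hat V$ is then plugged
into GLS for every state $i$:
$(\hat\beta_i, \hat\gamma) = ([x_i\, C]'\hat V^{-1}[x_i\, C])^{-1}
[x_i\, C]'\hat V^{-1} y$. $\hat V$ is Cholesky-factorized once per sample
and all $m$ solves reuse the factorization; the explicit inverse is never
formed. A test asserts that the one-shot null covariance reproduces
per-state full REML refits (profile correlation > 0.99) and that the
factorized GLS equals the textbook matrix-inverse formula to $10^{-8}$.

REML itself profiles $\theta$ on a grid ($\{0, 0.05, \dots, 0.95\}$ by
default). At each grid point the variance *ratio*
$\phi = \lambda^2/\sigma_e^2$ is optimized one-dimensionally with
$\sigma_e^2$ concentrated out in closed form; $\phi = 0$ (no random
effect) is always evaluated so the boundary is reachable exactly.
Likelihood evaluations use a rank-$k$ identity — an SVD of
$Z R_\theta^{-1}$ with $R_\theta$ the Cholesky factor of $D - \theta W$ —
so one evaluation costs $O(nk)$ after an $O(nk^2)$ setup per grid point.
A grid point where $D - \theta W$ is not positive definite is skipped;
failure at every grid point is a hard error.

### A note on the identifiability of $\theta$

Simulation shows that $\hat\lambda^2$ and $\hat\sigma_e^2$ recover their
generating values closely (within a few percent on average at
$n = 500$ genes, $k = 100$ cells), while $\hat\theta$ does not: once
$\lambda^2$ is profiled, the restricted likelihood is nearly flat in
$\theta$ (fractions of a log-likelihood unit across the whole domain under
the default Gaussian kernel, at any sample size we examined). This is a
property of the model, not of the optimizer — the dense-matrix likelihood
shows the same flatness. The flip side is that the deconvolution output is
insensitive to $\theta$, because $V$ itself barely changes; the flat
direction is absorbed by $\lambda^2$. We report $\hat\theta$ but advise
against interpreting it.

## Testing the random-effect component

$H_0\!: \lambda^2 = 0$ sits on the boundary of the parameter space, so the
likelihood-ratio statistic is referred to the standard 50:50 mixture of a
point mass at zero and $\chi^2_1$: $p = \tfrac12 P(\chi^2_1 \ge
\mathrm{LRT})$, equal to $0.5$ when the estimate hits the boundary.

## Smoothing and rescaling

Raw per-state estimates are noisy; the package smooths them over the
trajectory (LOESS with local quadratics, default span 0.5, or a symmetric
$q$-nearest-state average, $q = \max(3, m/10)$). The span default was set
by benchmarking on the synthetic test bed: at $m = 50$ states a 0.35 span
leaves visibly under-smoothed profiles and measurably lower concordance
with the planted truth, while 0.5 resolves all four benchmark shapes;
both are exposed as parameters. Smoothing happens before rescaling.

The raw estimates are deliberately unconstrained. Because each
$\hat\beta_i$ measures state $i$ against the CAR-smooth background carried
by the random effect, a whole profile can sit on a common negative offset.
For interpretation the profile is rescaled to $[0,1]$ with unit sum. The
default reading ("min–max") shifts the minimum to zero and divides by the
total, preserving the relative shape; an alternative ("truncate") clips
negatives at zero first. We made min–max the default after observing, on
noise-free mixtures where the raw profile matches the truth at correlation
0.99, that truncation discards the sub-offset flanks and caps the
concordance correlation around 0.67 while min–max restores it.

# The synthetic test bed

Everything above is validated on data the package generates itself.

* `generateSyntheticReference()` builds a counts matrix with a focal type
  whose cells carry pseudotime $\sim U(0,1)$ and planted signature genes
  with smooth mean curves (monotone up, monotone down, and Gaussian bumps
  whose centers tile the trajectory), negative-binomial noise
  (size 2, typical UMI overdispersion), and other cell types with their
  own perturbed mean profiles. Defaults — 1,000 genes of which 300 are
  trajectory-associated, 1,200 cells of which 60% are focal (about 14
  cells per state at $m = 50$), three cell types — were chosen once as a
  realistic down-sampled reference and frozen.
* `synthesizeBulk()` mixes source cells according to one of four abundance
  shapes over $L$ uniform states — increasing $t^k$, decreasing
  $(1-t)^k$, unimodal $[-(t-0.5)^2 + 0.25]^k$, bimodal
  $\sin(3\pi t) - \min(\sin(3\pi t))$ — normalized to unit sum, with
  $n = \min\{n : n a_l \ge 1\ \forall a_l \ne 0\}$ cells drawn with
  replacement (`round` half-up per state), averaged, and multiplied by
  log-normal noise (default sd 0.2 on the natural-log scale, exposed as a
  sweep parameter).
* `evaluateAccuracy()` scores estimates against the known truth by the
  concordance correlation coefficient (population moments), Pearson's $r$
  and RMSD.

What the generator does **not** emulate: batch structure beyond a single
multiplicative noise, platform-specific dropout, doublets, ambient RNA,
multi-branch trajectories, or the cross-individual expression correlation
that real cohorts show. Passing the synthetic benchmark therefore
demonstrates correctness of the machinery and recoverability under the
stated noise model — not performance on any particular real tissue. In
particular, the advantage of fitting every focal cell individually over
simply binning (the fixed-effect and random-effect bin ablations in
`deconvolveBinned()`) is modest on this clean synthetic data, whereas
heterogeneous real references are precisely where per-cell weights pay
off; the test bed asserts only the direction of the ordering.

```{r example, eval = FALSE}
ref <- generateSyntheticReference(seed = 1)
pb  <- synthesizeBulk(ref, shape = "bimodal", L = 50, noiseSd = 0.2, seed = 2)
ab  <- deconvolve(as.matrix(pb@y), ref, mStates = 50, nSignature = 300)
evaluateAccuracy(abundances(ab)[, 1], pb@truth)
```

# Signature genes

Signature genes should be associated with the trajectory, and spread along
it. After removing genes expressed in fewer than 10% of focal cells
(inclusive boundary; the filter is idempotent), each gene is regressed on
pseudotime with a natural cubic spline (4 df) and ranked by the F
statistic. Selection is balanced along the trajectory: among genes passing
a BH $q < 0.05$ association filter, the location of the fitted peak bins
genes into 10 trajectory segments, and segments are drained round-robin in
descending F order until $n$ genes are chosen (global F rank fills any
shortfall). The significance filter is the package's own refinement:
balancing raw per-segment quotas lets noise genes displace true trajectory
genes whenever the informative peaks cluster in a few segments. The
procedure is deterministic and invariant to cell ordering (ties in
pseudotime break by cell id).

# Group differences: MANOVA-Pro and its permutation calibration

To compare cell-state abundance distributions between groups, each
sample's per-state profile is summarized by a polynomial fit
$\beta_j = T b_j + e$ on pseudotime rescaled to $[0,1]$ (default degree 2,
i.e. $k = 3$ coefficients), and the coefficient vectors are compared
across groups by a Pillai-trace MANOVA with the classical F approximation:
$s = \min(g-1, k)$, $m^\* = (|k - (g-1)|-1)/2$, $u = (\sum_j n_j - k - g -
1)/2$, $F = \Lambda(2u+s+1) / [(s-\Lambda)(2m^\*+s+1)]$ on $s(2m^\*+s+1)$
and $s(2u+s+1)$ degrees of freedom. The implementation is checked against
`stats::manova`'s Pillai statistic to $10^{-8}$.

The profile fed to the test is the *unconstrained* (smoothed) one. A
unit-sum profile cannot be used: with an intercept in $T$, residuals sum
to zero, so the normalization constraint becomes an exact affine
constraint on the coefficients and the SSCP matrices are singular by
construction.

On independent data the parametric test holds its size, but abundance
estimates are correlated across samples (gene expression is), and the
correlation can differ between groups — which inflates any parametric
test applied to them. The calibrated alternative shuffles the
signature-gene labels of the reference (a joint row permutation of $X$,
$C$, $Z$ against the untouched bulk), re-runs the entire deconvolution
and the MANOVA-Pro F, and reports the add-one empirical p-value
$(1 + \#\{F_{perm} \ge F_{obs}\})/(1 + n_{perm})$, default 1,000
permutations. Group-label permutation is available behind
`shuffle = "labels"`. Calibration is verified on 200 whole-pipeline null
repetitions at reduced size (8 samples, 8 states, 60 signature genes, 19
permutations each — sizes chosen to make 200 repetitions a routine test).

# Cell-state-dependent eQTLs

Per sample, the normalized abundance is summed within each trajectory
quartile (Q1–Q4). For each gene, each variant within ±1 Mb of the TSS
(closed interval, 1-based) with minor-allele frequency ≥ 0.05 and each
quartile, the model

$$y_i = x_i\alpha + s_i\beta + x_i s_i \gamma + \textstyle\sum_j c_{ij}\delta_j + e_i$$

is fitted by OLS, with expression and abundance rank-based
inverse-normal transformed (Blom offset $3/8$, average ranks for ties) and
the top expression principal components (default 15) plus any user
covariates as $c$. The reported p-value is the two-sided t test on
$\hat\gamma$; a constant abundance row is refused as unidentifiable rather
than silently dropped. Within each gene the minimum p is Bonferroni-scaled
by the number of tested variants — a conservative, dependency-free
effective-test correction — and BH FDR across genes calls csd-eGenes at
FDR < 0.05. Hidden-factor correction by expression PCs and the
Bonferroni stand-in are the package's choices where the field uses
heavier external tooling; both are exposed as parameters.

Quartile abundance uses the *sum* of normalized state abundances in the
quartile (the mean differs only by a constant factor per quartile and
changes nothing after the inverse-normal transform). One model is fitted
per quartile, matching the single-$s_i$ regression above.

Enrichment of a query set (e.g. lead csd-eQTLs) in an annotation score
(e.g. trajectory-association $\chi^2$ of chromatin peaks — consumed as a
precomputed input) is the query mean over the mean of 1,000 control-set
means, controls matched on count and on the query's MAF distribution over
10 equal-width bins on $[0.05, 0.5]$. Its sampling variance uses the
delta method under $\operatorname{cov}(x,\bar y) \approx 0$ and
$\operatorname{var}(x) \approx \widehat{\operatorname{var}}(y)$:
$\operatorname{var}(x/\bar y) \approx (x/\bar y)^2
[\widehat{\operatorname{var}}(y)/x^2 +
\widehat{\operatorname{var}}(y)/(m\bar y^2)]$, giving the 95% CI. A test
confirms the delta variance tracks the empirical variance of the fold
across re-drawn null queries within 25%.

# Numerical and degenerate-input choices

* Ties in pseudotime: stable cell-id order. Identical coordinates
  everywhere: warning, all off-diagonal weights 1 (valid limit).
* Singular per-state GLS design (e.g. $x_i$ collinear with $C$): that
  state becomes `NA` with a warning; the sample still completes.
* All-nonpositive constant profiles cannot be rescaled: explicit error.
* Equal-count state bins use `diff(round(seq(0, k, length.out = m+1)))`,
  so sizes differ by at most one cell.
* Config files are flat `key = value` text; unknown keys are errors.

# Problem sizes used by the test suite

The suite regenerates all data at run time: oracle-equivalence checks at
50 genes × 30 cells; REML recovery at 500 genes × 100 cells × 50
replicates; end-to-end accuracy on the default reference (1,000 × 1,200)
with three mixtures per shape; permutation calibration with 200 repetitions
of an 8-sample pipeline; eQTL size on 1,000 gene–variant pairs at
$n = 500$ and power on planted $\gamma = 0.5$. These sizes are the
package's validation conditions, stated here so results are reproducible.

# Known limitations

* One-dimensional, single-branch trajectories only.
* Abundance estimates are relative within the focal type, not absolute
  cell counts; non-negativity is imposed only at the rescaling step.
* $\theta$ is reported but weakly identified (above).
* The eQTL module assumes 0/1/2 minor-allele dosages and does not estimate
  population structure; genotype PCs must be supplied as covariates.
* The permutation group test re-runs the full deconvolution per
  permutation; at 1,000 permutations and cohort scale this is the
  dominant cost (it parallelizes trivially across permutations, which the
  current implementation does not do).
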