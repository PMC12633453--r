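---
title: "Shrinkage-prior variable selection for spatial negative binomial counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shrinkage-prior variable selection for spatial negative binomial counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spanbvs)
```

## The model

`spanbvs` fits Bayesian negative binomial (NB) regression to counts observed
at `n` spatial locations with a potentially high-dimensional feature vector
per location. For location `i` with count `y_i` and feature row `K_i`
(first entry 1, the intercept),

$$
y_i \sim \mathrm{NB}(\psi_i, r), \qquad
\psi_i = \frac{e^{\eta_i}}{1 + e^{\eta_i}}, \qquad
\eta_i = K_i^\top \beta + \phi_i + o_i,
$$

where `r > 0` is the dispersion, `o_i` an optional offset (for rate models,
`log P_i - log 100000` with `P_i` the population at risk), and `phi` a
spatial random effect. The NB pmf is proportional to
$\psi^{y}(1-\psi)^{r}$, so the implied mean is $r\,e^{\eta}$ and the
variance exceeds the mean for every finite `r` (overdispersion). This
logit-scale parameterisation is the one compatible with Pólya-Gamma (PG)
data augmentation: introducing $\omega_i \sim \mathrm{PG}(y_i + r, \eta_i)$
makes the conditional likelihood Gaussian in $\eta$, with pseudo-response
$\kappa_i = (y_i - r)/2$ and precision $\omega_i$. Every full conditional in
the sampler is then available in closed form.

### The spatial random effect

`phi` carries an intrinsic conditional autoregressive (ICAR) prior on a
user-supplied neighbourhood graph: precision $\nu Q$ with $Q = D - W$, `W`
the adjacency matrix (queen contiguity on lattices: edge- or corner-sharing
cells are neighbours) and `D` the diagonal of neighbour counts. `Q` is rank
deficient by one per connected component, so a nugget $\epsilon = 10^{-8}$
is added to the diagonal and the field is recentred to sum to zero within
each component after every draw, which separates it from the intercept. The
multiplier $\nu$ gets a conjugate Gamma(0.1, 0.1) prior, updated as
$\nu \mid \phi \sim \mathrm{Gamma}(a_\nu + (n - k)/2,\; b_\nu + \phi^\top Q \phi / 2)$
with `k` components. Note the direction implied by the precision algebra:
*smaller* $\nu$ means a weaker penalty on neighbour differences and hence a
*larger-amplitude* spatial field; the simulation presets use
$\nu \in \{0.1, 0.25\}$ as the strong- and weak-dependence settings
respectively.

### Shrinkage priors on the coefficients

Four families regularise the non-intercept coefficients (the intercept
always keeps a fixed N(0, 100) prior and is never selected):

* **Horseshoe (`hs`)**: $\beta_j \sim N(0, \tau^2\lambda_j^2)$ with
  half-Cauchy(0, 1) global ($\tau$) and local ($\lambda_j$) scales.
* **Spike-and-slab (`ss`)**: $\beta_j$ is zero with probability
  $1 - \delta_j$, or drawn from the Gaussian slab $N(0, \sigma^2_{slab})$;
  $\delta_j \sim \mathrm{Bern}(\omega)$,
  $\omega \sim \mathrm{Beta}(a_\omega, b_\omega)$,
  $\sigma^2_{slab} \sim \mathrm{IG}(a_s, b_s)$.
* **Grouped horseshoe (`grouped_hs`)**: with features in known groups,
  $\beta_{gk} \sim N(0, \zeta^2\tau_g^2\lambda_{gk}^2)$, all three scales
  half-Cauchy: a global-global $\zeta$, a group scale $\tau_g$, and a local
  scale $\lambda_{gk}$.
* **Grouped spike-and-slab (`grouped_ss`)**: the hybrid family. The slab
  variance factorises as $\zeta^2\tau_g^2$ (half-Cauchy $\zeta$, $\tau_g$),
  and per-group inclusion fractions $w_g \sim \mathrm{Beta}(a_\omega,
  b_\omega)$ drive the indicators, so group relevance is learned on the
  horseshoe side while individual features are selected through posterior
  inclusion probabilities.

Singleton groups drop the redundant hierarchy level: the grouped horseshoe
pins $\lambda_{gk} = 1$, the grouped spike-and-slab pins $\tau_g^2 = 1$
(its singleton slab variance is exactly $\zeta^2$).

Half-Cauchy scales are sampled with the inverse-gamma parameter expansion
($x \sim C^+(0,1)$ iff $x^2 \mid a \sim \mathrm{IG}(1/2, 1/a)$,
$a \sim \mathrm{IG}(1/2, 1)$), so every scale update is inverse-gamma. In
the grouped spike-and-slab, $\tau_g$ and $\zeta$ condition on the currently
*included* coefficients only; a group with no included members draws
$\tau_g$ from its hyperprior conditional, keeping the chain irreducible so
the group can re-enter.

### Dispersion

The dispersion needs its own augmentation to stay within closed-form
updates; we use the Chinese-restaurant-table (CRT) scheme: latent table counts
$l_i \sim \mathrm{CRT}(y_i, r)$ give the conjugate draw
$r \sim \mathrm{Gamma}(a_r + \sum_i l_i,\; b_r + \sum_i \log(1 + e^{\eta_i}))$
with a Gamma(1, 1) prior. `fixedR` freezes `r` instead. For the very large
counts that heavy-tailed NB designs produce, the CRT draw samples its first
1000 seating indicators exactly and replaces the remainder — individually
tiny occupation probabilities — by one Poisson variate with the matching
mean $r(\psi_0(r + y) - \psi_0(r + 1000))$, bounding the per-observation
cost while keeping the mean exact.

## The Gibbs sweep

Each sweep updates, in fixed order: PG latents; coefficients — a joint
multivariate Gaussian draw for the continuous families, and for the
spike-and-slab families a collapsed per-coordinate indicator scan in
randomized order (each $\delta_j$ drawn with $\beta_j$ integrated out of
the PG-Gaussian likelihood) followed by a joint refresh of the included
set; shrinkage scales; the spatial field and $\nu$; then `r`. The joint
coefficient refresh matters under multicollinearity (the simulation designs
go up to within-block correlation 0.5), where purely coordinatewise updates
mix poorly. Initialisation is neutral and reproducible: $\beta = 0$,
$\phi = 0$, $r = 1$, all scales 1, $\delta \sim \mathrm{Bern}(0.5)$,
$\nu = 1$. Identical data, configuration, and seed give bit-identical
draws, and a checkpointed chain resumes to a bit-identical continuation
(the linear predictor is recomputed from the exact state at the start of
every sweep for this reason).

### Pólya-Gamma sampling

No PG sampler ships with base R, so the package implements one from the
exact weighted sum-of-gammas series
$\mathrm{PG}(b, c) = \tfrac{1}{2\pi^2}\sum_{k\ge1}
g_k / ((k - 1/2)^2 + c^2/(4\pi^2))$, $g_k \sim \mathrm{Gamma}(b, 1)$,
valid for any real shape $b > 0$ (needed because the NB augmentation uses
$b = y_i + r$ with real `r`). The first 40 terms are drawn exactly; the
tail — whose first two moments have closed forms via
$\sum_k ((k-1/2)^2 + h)^{-1} = \tfrac{\pi}{2\sqrt h}\tanh(\pi\sqrt h)$ and
its derivative — is replaced by one moment-matched Gamma variate. The draw
mean $(b/2c)\tanh(c/2)$ is exact; the distributional approximation is
confined to the <1% of mass in the tail. The test suite checks the sampler
against analytic means and variances, and (more stringently) the whole
Gibbs posterior against an exact-likelihood Metropolis run.

## Selection and evaluation

Spike-and-slab families report per-feature posterior inclusion
probabilities, $\mathrm{PIP}_j = S^{-1}\sum_s \delta_j^{(s)}$ over the `S`
retained draws; thresholding at 0.5 is the median probability model, and
0.6 is the stricter threshold used in applications. Horseshoe families
select by zero-exclusion of equal-tailed credible intervals (ETI). For
ROC analysis the horseshoe score is concretised as the *maximal
zero-excluding ETI level* on the grid 0.01, ..., 0.99, 0.999 — a bounded,
monotone score that orders features exactly as interval-width thresholding
does, which is the open design point the interval-based rule leaves
unspecified. AUC is the rank-based Mann-Whitney statistic with ties counted
half, verified in the tests against brute-force pair enumeration and an
independent ROC implementation.

Convergence is screened with the Geweke statistic (first 10% vs last 50%
of each trace, spectral-density-at-zero standard errors from a
Bartlett-windowed autocovariance sum); `|z| > 2` flags a parameter.

## The simulation engine

`simulateScenario()` reproduces three lattice designs with exactly ten
non-null coefficients each, NB outcomes at `r = 1` (configurable), and
locations on a 10 x 5 (n = 50) or 10 x 10 (n = 100) queen-contiguity grid:

* **sim1** — AR(1)-correlated features (`N(0, 0.1 Sigma)`,
  `Sigma_jk = rho^|j-k|`), ten random signals fixed at 2, an ICAR field at
  $\nu Q + 10^{-8}I$. Benchmarks the value of modeling the spatial effect.
* **sim2** — independent AR(1) blocks of five (one remainder block of four
  when `p - 1` is not a multiple of five), signals `Unif(0.5, 2)` placed in
  two fully active groups ("full") or three partially active groups with
  4/3/3 active members ("partial"); no spatial field. Benchmarks grouped
  vs ungrouped priors. Because exactly ten signals are required, the two
  fully active groups are drawn among the size-five groups.
* **sim3** — first `p/2` features in AR(1) blocks of five; the remaining
  `p/2 - 1` are equicorrelated singletons (pairwise 0.5); ten signals of
  size 4 split evenly between the halves (one full group, or 3 + 2 across
  two groups under "partial"); ICAR field as in sim1. Benchmarks
  singleton-aware bi-level shrinkage under spatial dependence.

Feature generation, signal placement, the spatial field, and the outcome
draw consume dedicated seed streams derived from the study seed, so any of
them can be varied independently and every preset regenerates
bit-identically. What the generator deliberately does *not* emulate:
real-data feature marginals (survey percentages, gene expression),
between-group correlation, zero inflation, or irregular (non-lattice)
adjacency beyond what `readAdjacency()` ingests — so passing benchmarks
here demonstrate correct recovery under the stated Gaussian/AR designs,
not performance on any particular applied dataset.

## Numerical choices and degenerate inputs

* Nugget $10^{-8}$ on the ICAR precision (configurable); the spatial
  conditional adds the PG precisions, so its Cholesky is well conditioned
  in practice and a failure aborts with the offending dimension.
* Sum-to-zero is enforced by recentring per graph component after every
  draw (soft constraint + centring); retained fields satisfy the
  constraint to 1e-10 and disconnected graphs are allowed, with the rank
  deficiency equal to the component count.
* Single-cell grids, self-loop edges, unknown node labels, asymmetric
  adjacency matrices, overlapping group files, non-positive entries under a
  log transform, and constant columns under standardisation are all hard
  errors, not silent fixes; features absent from a group file become
  singletons with a warning.
* Inclusion-indicator ties are avoided by drawing coordinates in a fresh
  random order each sweep; the selection boundary is `>=` at the stated
  threshold.
* A storage guard refuses runs whose retained draws would exceed a
  configurable cap (default 1 GB); thinning is the intended remedy.

## Problem sizes used in the checks

The test suite and the acceptance script run scaled-down versions of the
benchmark designs chosen as the smallest configurations that still exercise
every code path and leave clear statistical margins: n = 100, p = 50
studies with 4000-sweep chains and 10 replicate seeds for the two
directional comparisons (spatial effect on/off; grouped vs ungrouped), a
25-observation toy against a 200,000-step exact-likelihood Metropolis
oracle, exhaustive 2^3- and 2^4-model enumeration oracles at n = 12, and
100,000-draw moment checks for the Pólya-Gamma and ICAR samplers.

## Known limitations

* The dispersion `r` and the spatial field compete for unexplained
  heterogeneity: under a strong field (nu = 0.1) with shrinkage-underfit
  coefficients, the posterior for `r` can sit well below the generating
  value on some replicates even though the exact likelihood at the true
  linear predictor peaks near it. This is a property of the joint
  posterior, not the sampler; chains initialised at the truth migrate to
  the same region.
* Proper CAR variants (Leroux/BYM), spatially varying coefficients,
  overlapping groups, zero inflation, and variational inference are out of
  scope.
* The grouped-horseshoe group-scale update conditions on all coefficients
  in the group (the family has no indicators); whether included-only
  conditioning would behave differently is untested here.
* Single-chain diagnostics only (Geweke + traces); no cross-chain R-hat.

## A worked example

```{r example, eval = FALSE}
study <- simulateScenario("sim3", n = 100, p = 50, nu = 0.25,
  case = "full", seed = 1)
fit <- fitNBSpatial(studyData(study), groupedSpikeSlabPrior(studyGroups(study)),
  graph = studyGraph(study), nIter = 10000, seed = 1)
head(selectFeatures(fit, pipThreshold = 0.6))
evaluateSelection(fit, study)$auc
diagnosticsReport(fit)$fractionPassing
```
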