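---
title: "Methods: Bayesian small-area SMR mapping with smrmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian small-area SMR mapping with smrmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smrmap)
```

## The problem

Crude small-area rates of a rare event (the motivating application is
suicide mortality across ~1900 Japanese municipalities observed over a
multi-year period) are dominated by Poisson noise: a village with two
hundred inhabitants and one event has a meaninglessly extreme rate.
`smrmap` implements the standard disease-mapping answer. Observed counts
are first turned into standardized mortality ratios (SMRs) by indirect
standardization, then smoothed with a Besag–York–Mollié (BYM)
hierarchical Poisson model over the municipality adjacency graph, and
finally related to a rural–urban gradient and socioeconomic covariates
through log-linear fixed effects reported as rate ratios with 95%
credible intervals.

## Indirect standardization

For area $i$ and stratum (gender × 10-year age band) $b$, reference
rates are pooled national ratios $r_b = \sum_i O_{ib} / \sum_i P_{ib}$
of events to person-years, and expected counts are
$E_i = \sum_b P_{ib} r_b$. The raw SMR is $O_i / E_i$; when the
reference rates come from the pooled data themselves,
$\sum_i E_i = \sum_i O_i$ exactly (self-standardization closure), which
the test suite asserts to $10^{-12}$ relative tolerance. Counts are
pooled over the whole study period before rates are computed;
year-by-year standardization is out of scope (closure would not hold
for it). Areas with $E_i = 0$ carry an explicit undefined flag instead
of an infinite or NaN SMR, and are dropped from the model likelihood
with a warning.

Gender- and age-group analyses (`all`, `0–39`, `40–59`, `60+`) restrict
both the observed counts and the reference-rate bands to the stratum,
so each stratified analysis is itself internally standardized.

## Dispersion and map summaries

Geographic spread is summarized by the 90%-range fold difference, the
ratio of the 95th to the 5th percentile of area SMRs — robust against
the unstable extremes of small areas. Quantiles use linear interpolation
between order statistics (the type-7 convention, the default of most
statistical software); the published convention rounds the ratio half-up
to one decimal, and `rangeRatio()` returns both the raw and rounded
value. The fold is undefined when the 5th percentile is zero (possible
for raw SMRs in sparse strata); the pipeline reports `NA` there rather
than failing.

Maps use seven categories symmetric on the log scale
($<0.50$, $0.50$–$<0.67$, $0.67$–$<0.90$, $0.90$–$<1.10$,
$1.10$–$<1.50$, $1.50$–$<2.00$, $\geq 2.00$), left-closed and
right-open, exported as GeoJSON properties with a blue/pale-yellow/brown
palette suggestion.

## Rurality deciles and covariates

Areas are ranked by descending population density and cut into ten
equal-count groups; decile 1 (highest density) is "most urban" and the
reference category of all rate-ratio tables. When the area count is not
divisible by ten the remainder goes to the leading groups
(largest-remainder allocation: 1887 areas yield seven groups of 189 and
three of 188), and density ties break by a stable sort on area id so
the assignment is reproducible.

Four socioeconomic covariates (percent single-person households,
percent unmarried adults, unemployment rate, percent with college
education) enter the adjusted model as z-scores. The two right-skewed
covariates (single-person households, college education) are
natural-log-transformed first. z-scores use the sample ($n-1$) standard
deviation and weight every municipality equally; population weighting
would be a defensible alternative, but equal weighting matches the
descriptive use of the covariates and is what we pin down.

## The BYM model

For each stratum,

$$O_i \sim \mathrm{Poisson}(E_i \theta_i), \qquad
\log \theta_i = \alpha + x_i^\top \beta + u_i + v_i,$$

with an intrinsic conditional autoregressive (ICAR) prior on the
structured field $u$,

$$p(u \mid \tau_u) \propto \tau_u^{(n-c)/2}
\exp\!\Big(-\frac{\tau_u}{2} \sum_{i \sim j} (u_i - u_j)^2\Big),$$

where $c$ is the number of connected components of the adjacency graph,
and iid $v_i \sim N(0, 1/\tau_v)$. The precision matrix is $Q = D - W$
(degree diagonal minus adjacency), rank-deficient by one per component;
identifiability comes from a sum-to-zero constraint on $u$ within each
component, with the flat-prior intercept $\alpha$ carrying the level.

Hyperpriors are $\tau_u, \tau_v \sim \mathrm{Gamma}(1,\ 5\times10^{-5})$
(shape, rate) — the conventional vague default of disease-mapping
software — and $\beta_j \sim N(0, 1000)$. The acceptance suite checks
that multiplying the Gamma rate by ten moves posterior-median rate
ratios by less than 0.02, so results do not hinge on this choice.

Three model variants are fitted by the pipeline per stratum: the
covariate-free model, whose posterior medians of
$\exp(\alpha + u_i + v_i)$ are the **smoothed SMRs**; the decile-only
model (**unadjusted** rate ratios); and the decile + covariates model
(**adjusted** rate ratios), whose medians of $\exp(u_i + v_i)$ are the
**residual SMRs** — spatial variation the observed covariates do not
explain. Publishing practice is ambiguous about whether smoothed maps
come from a covariate-free or a rurality model; we support both and
default to covariate-free, which is the cleaner definition of "smoothed
SMR". A coefficient is starred when its equal-tailed 95% credible
interval excludes 1; the posterior point estimate is the median, which
is invariant under the $\exp$ transform.

## MCMC sampler

Estimation is by MCMC (a nested-Laplace approximation engine is
deliberately out of scope; MCMC is exact in the limit and directly
testable against small-model oracles):

* **Precisions**: conjugate Gibbs draws,
  $\tau_u \mid u \sim \mathrm{Gamma}(a + (n-c)/2,\ b + S_u/2)$ with
  $S_u = \sum_{i\sim j}(u_i-u_j)^2$, and
  $\tau_v \mid v \sim \mathrm{Gamma}(a + n/2,\ b + \sum_i v_i^2/2)$,
  verified distributionally (Kolmogorov–Smirnov at $n = 10^5$) against
  the analytic full conditionals.
* **Unstructured field** $v$: the sites are conditionally independent,
  so all $n$ single-site random-walk Metropolis updates run as one
  vectorized pass, each site with its own adaptive scale targeting 0.44
  acceptance.
* **Structured field** $u$: single-site random-walk Metropolis, executed
  by graph-coloring classes — all sites of one color are mutually
  non-adjacent, so their full conditionals depend only on the other
  colors and can be updated simultaneously; this is algebraically the
  same single-site update, vectorized. After every sweep $u$ is
  re-centered to zero mean per component, the intercept absorbing the
  size-weighted shift (exact for a connected graph, which sea-route
  edges guarantee in the motivating data).
* **Fixed effects** $(\alpha, \beta)$: a joint Metropolis–Hastings step
  with a Gaussian independence proposal centered at the conditional mode
  (found by offset-adjusted iteratively reweighted least squares — the
  Poisson log-link conditional is strictly concave, so the mode is
  unique) with the curvature there. A plain adaptive random walk was
  tried first and mixed an order of magnitude worse at realistic event
  counts (effective sample sizes of ~10 per 3000 sweeps for a 10-dim
  block); the mode-centered proposal accepts at ~0.97 and delivers
  near-independent block draws.

Adaptation of the single-site scales runs in batches of 50 sweeps during
burn-in only, so retained draws come from a fixed, Markovian kernel.
Initial fields are small random draws rather than zeros (a zero field
would make the first Gibbs precision draw explode off the prior rate,
stalling adaptation). A fixed seed makes every draw bit-reproducible;
chain $k$ of a multi-chain run uses `seed + 1000(k-1)`.

Convergence is monitored by split-chain $\hat R$ (flagged above 1.05)
and an effective-sample-size estimate based on Geyer's initial monotone
positive sequence; summaries warn when a reported quantity has fewer
than 200 effective draws. These diagnostics are implemented in the
package (standard formulas) rather than imported.

## Synthetic data generator

Because the real municipality tables are external downloads, the
package carries a generator that emulates the statistical structure the
analysis assumes, with ground truth retained for recovery experiments.
Defaults were chosen once, as the study conditions, and are:

* **Graph**: a 20×20 four-neighbor lattice (400 areas; recovery fits run
  in seconds), optionally with detached island blocks reconnected by
  single sea-route edges to exercise the extra-edge path.
* **Density**: log-uniform over 1.6–21,898 persons/km² (four orders of
  magnitude, the published descriptive range), spatially autocorrelated
  by rank-mapping a smoothed latent score onto the log-density grid.
* **Person-years**: proportional to `density^0.5` with lognormal
  jitter, scaled so the median area has 2.7×10⁵ person-years (a median
  population of ~30,000 followed for nine years). The square-root
  exponent reflects that dense municipalities occupy little land, and
  keeps the smallest areas' expected counts near 3 so raw-SMR
  percentiles stay defined, while person-years still span more than two
  orders of magnitude.
* **Age/gender structure**: a 50/50 gender split across nine 10-year
  bands with an aging-population profile, and baseline event rates
  rising steeply out of childhood (higher for males), so stratified
  analyses are meaningful.
* **Covariates**: four percent-scale variables mixing a density
  gradient, a smooth spatial field and noise; two are lognormal
  (right-skewed) and become symmetric (|skewness| < 0.5) after the log
  transform, as the transform step assumes.
* **Random effects**: a constrained ICAR field ($\tau_u = 25$) sampled
  by spectral decomposition of $Q$ restricted to its row space, and iid
  noise ($\tau_v = 400$), giving smoothed-SMR fold differences around
  1.5–1.8, the magnitude seen in national suicide data.

What the generator does **not** emulate: real geography (a lattice is
not Japan), the empirical joint distribution of the covariates,
municipal boundary changes over time, and any space–time trend. Passing
recovery tests therefore show that the estimator is correct under the
model's own assumptions at realistic scales — not that the model is
adequate for any particular real dataset.

## Numerical choices and degenerate inputs

* Eigenvalues below $10^{-9} \times \lambda_{\max}$ of $Q$ are treated
  as the null space when sampling the constrained ICAR field.
* `E_i = 0` areas: excluded from the likelihood (warning), retained in
  the prior; their effects are informed by neighbors only.
* Isolated areas are permitted with a warning; under the constrained
  ICAR prior an isolated area is its own component with effect pinned
  to zero.
* Asymmetric neighbor-list entries are symmetrized by union with a
  warning (the neighbor relation is symmetric by definition; hand-edited
  files often drop one direction). Neighbor files use literal area ids,
  never 1-based ordinal indices, so joins against CSV tables are
  unambiguous.
* Fold-difference rounding is half-up (1.658 → 1.7; banker's rounding
  would print 1.6 for 1.65).
* The linear predictor is capped at 40 inside the block update to avoid
  overflow in pathological proposals; the cap is unreachable in
  equilibrium.

## Problem sizes

The shipped tests and the acceptance script run the full estimator at
the default 400-area scale with 2,000–4,000 sweeps per chain and 10–20
replicate simulate-fit cycles per experiment — sizes at which the
recovery experiments are decisive (credible-interval coverage within
binomial tolerance of nominal) while a complete run stays in the
minutes range on a single core. Larger systems (the generator is tested
to ~10⁴ areas for graph operations) mainly stress the dense spectral
ICAR sampler, which would be the first thing to replace (by sparse
Cholesky with constraint correction) for national-scale simulation.

## Known limitations

* The BYM parameterization is the classic one; reparameterizations with
  interpretable mixing weights (Leroux, BYM2) are out of scope.
* No spatio-temporal modelling; counts are pooled over the period.
* Credible intervals for raw SMRs are intentionally absent (raw SMRs
  are reported only as descriptive input to the smoothing story).
* Model comparison (DIC/WAIC) is not implemented.
* The rurality index is a population-density decile; commuting-zone or
  remoteness indices would need their own covariate input.
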