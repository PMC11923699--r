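---
title: "Model-based geostatistical mapping of childhood growth faltering"
author: "geofalter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based geostatistical mapping of childhood growth faltering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geofalter)
```

## The model and its assumptions

`geofalter` estimates fine-scale prevalence of stunting, underweight and
wasting from cluster-survey anthropometry. The observation unit is an
individual child's continuous z-score (HAZ, WAZ or WHZ against the WHO
2006 growth standards), observed at the GPS location of the child's
survey cluster. For child $j$ at cluster $x_i$:

$$Y_{ij} = \alpha + \beta^\top D(x_i) + S(x_i) + U_{ij},$$

with $S(\cdot)$ a zero-mean stationary isotropic Gaussian process with
variance $\sigma^2$ and exponential correlation
$\rho(u) = \exp(-u/\phi)$ in Euclidean km, and
$U_{ij} \sim N(0, \omega^2)$ iid. The assumptions that matter:

* **Gaussian outcomes.** Z-scores are approximately Gaussian by
  construction; modelling them directly (rather than dichotomizing at
  −2 and fitting a binomial spatial model) retains information, and
  prevalence is recovered afterwards as an exceedance probability of
  the fitted Gaussian predictive distribution.
* **Cluster-level spatial resolution.** All children in a cluster share
  one location, hence one draw of $S$; the full covariance between
  individuals is $\sigma^2 e^{-u_{ii'}/\phi} + \omega^2
  \mathbf{1}[i=i', j=j']$.
* **Exponential correlation** (Matérn with smoothness 1/2). The
  *practical range* — where correlation reaches 0.05 — is reported as
  $3\phi$ (the conventional approximation; `practical_range(phi,
  exact = TRUE)` gives $-\phi\log 0.05$).
* **Planar km geometry.** $\phi$ is in km and distances are Euclidean,
  so inputs must be in a projected planar system; the synthetic world
  is generated directly in km.

## Estimation: exact likelihood, concentrated profile

The model is linear-Gaussian, so the marginal likelihood of
$(\beta, \sigma^2, \phi, \omega^2)$ is available in closed form; we
maximize it exactly rather than by Monte Carlo. Two implementation
choices matter for robustness and speed:

1. **Blocked algebra.** With $n$ children in $m \ll n$ clusters,
   $\Sigma = \omega^2 I_n + Z(\sigma^2 R)Z^\top$. Writing
   $E = \mathrm{diag}\sqrt{n_i/\omega^2}$ and
   $G = I + \sigma^2 E R E$, both $\log|\Sigma|$ and $\Sigma^{-1}v$
   need only one $m \times m$ Cholesky per evaluation, and $G$ is
   positive definite even if $R$ is singular (duplicate clusters). The
   test suite enforces agreement with the dense $n \times n$ density to
   $10^{-8}$.
2. **Concentration.** With $\Sigma = \nu^2 V(\rho, \phi)$,
   $\rho = \sigma^2/(\sigma^2+\omega^2)$, both $\beta$ (by GLS) and the
   total variance $\nu^2$ have closed-form maximizers, leaving a
   2-parameter numerical search over $(\mathrm{logit}\,\rho, \log\phi)$
   (1-parameter Brent for the non-spatial variant). Optimization uses
   Nelder-Mead from up to five dispersed, variogram-informed starts
   (nugget from within-cluster variance, sill from the variance of
   cluster means, range from a tenth of the domain diameter), because
   the likelihood in $\phi$ can be flat or multimodal.

Confidence intervals: coefficients from the GLS covariance at the
maximum; variance parameters by Wald intervals on the log scale,
back-transformed, which produces the familiar asymmetric intervals for
$\sigma^2$, $\phi$, $\omega^2$. Two-sided Wald p-values at the 5% level
are reported for $\beta$; no multiplicity correction is applied.

### When $\phi$ is not identifiable

If residual variation has no spatial structure, any $\phi$ fits equally
well. `geofit(check_phi = TRUE)` re-maximizes the likelihood over a
log-spaced grid of $\phi$ spanning two orders of magnitude around the
estimate; if this profile varies by less than 0.01 log-likelihood
units, $\phi$ is reported non-identifiable and a compound-symmetry
fallback (iid cluster effects — the $\rho(u) \equiv 0$ limit) is fitted
for AIC comparison. The 0.01 threshold is deliberately strict: sampling
noise alone produces profile wiggles well above it, so only a truly
flat (boundary) profile is flagged. The `empirical_variogram()` of
cluster-mean residuals, with a permutation envelope under spatial
independence, is the complementary graphical diagnostic.

## Lagged covariates and AIC selection

Monthly covariates enter the design at a lag $d$ relative to each
child's birth month: the covariate value at the child's location in
calendar month $b_j - d$, $d = 0,\dots,12$. `scan_lags()` substitutes
one lag at a time into the model (other covariates fixed), refits, and
selects the lag with minimum AIC ($2k - 2\ell$); ties within $10^{-6}$
go to the shorter lag (temporal parsimony). Lags are tested one at a
time because neighbouring lag columns are highly correlated; a joint
fit would split the effect arbitrarily. Whether lag 0 (the birth month
itself) belongs in the candidate set is a substantive choice the caller
makes via `lags`; both `0:12` and `1:12` are supported, `1:12` being
the default. Warm starts (variance parameters from the previous lag's
fit) make the scan cheap without changing the maximizer.

The SPEI accumulation timescale is chosen *before* lag scanning by
Pearson correlation of candidate SPEI series with a vegetation index
over pooled (location, month) pairs (`select_spei_timescale()`), ties
to the shorter timescale. Pooling is the default; averaging
per-location correlations is available (`per_location = TRUE`) since
the choice between the two is not dictated by theory. Redundant
covariate pairs (NDVI vs EVI, elevation vs slope) are reported by
`covariate_correlation_report()` rather than dropped by rule — which
member to keep is a configuration decision.

## Prediction, prevalence and aggregation

Prediction is plug-in kriging: MLEs treated as known. Cluster-mean
residuals are sufficient for $S$, so with
$\bar\Sigma = \sigma^2 R + \mathrm{diag}(\omega^2/n_i)$ the kriging
mean and variance at grid point $x$ are $c(x)^\top\bar\Sigma^{-1}\bar r$
and $\sigma^2 - c(x)^\top\bar\Sigma^{-1}c(x)$. Parameter uncertainty is
not propagated (standard practice in model-based geostatistics;
a parametric bootstrap via `simulate.geofit()` is the route if it is
needed). Grid covariates are standardized with the *training* means and
SDs — re-standardizing on the grid would silently rescale $\beta$.

Prevalence per cell is
$\Phi\!\big((-2 - m(x))/\sqrt{v(x) + \omega^2}\big)$, exact under the
model. The conditional-simulation path (joint draws of $S$ over the
grid, averaging the nugget-conditional CDF) is retained for two
reasons: it cross-validates the closed form (the suite requires
agreement within 3 Monte Carlo SEs cellwise) and it is the correct tool
for nonlinear functionals of jointly dependent cells. Default 1000
draws, explicit seed, minimum 500.

Cases are prevalence × under-5 population per cell; districts get
$\sum p \cdot \text{pop}$ and the population-weighted mean prevalence.
Cell-to-district assignment is by cell-center containment (even-odd
rule) — simple, conservative and exactly conservation-preserving under
any partition; area-weighted cell splitting is out of scope. Cells
outside all polygons are counted and reported, never silently dropped.

## The synthetic world

The generator replaces restricted-access survey data with a stated,
fixed world; its defaults are not tuning knobs.

* **Survey design.** 696 clusters drawn uniformly on a 500 × 500 km
  domain (the real survey's population-proportional sampling needs a
  census frame; uniform is the neutral default), 5–15 children per
  cluster (configurable; the real survey averaged ~7.5).
* **Truth.** HAZ-like parameters $\alpha = -1.23$, $\sigma^2 = 0.15$,
  $\phi = 18.28$ km, $\omega^2 = 2.02$, with per-SD effects such as
  0.06 for SPEI lagged 3 months.
* **Covariates.** Gaussian random fields with exponential spatial
  correlation. Monthly series have a 12-month sinusoidal seasonal mean
  plus spatially correlated anomalies independent between months.
  SPEI-like series use amplitude 0 and unit SD — a standardized anomaly
  index has no seasonal cycle by construction — which also makes lag
  columns nearly uncorrelated; rainfall-like series use amplitude 1
  with unit anomaly SD (seasonal swing comparable to anomaly spread, a
  realistic regime for equatorial rainfall). Field ranges (60–150 km)
  are ordered as vegetation < drought index < rainfall < temperature.
* **Population.** A log-Gaussian clustered raster (or uniform option)
  scaled to a requested total (default 7.2 million under-5s, a
  national scale), integerized by largest remainder so the total is
  exact.
* **Determinism.** One integer seed drives every stage; identical
  configurations give identical outputs, a property the suite asserts.

What a green test does *not* establish: the generator draws from the
model itself, so recovery tests validate the estimation machinery, not
the model's adequacy for real anthropometry (no survey weights, no GPS
displacement, no non-Gaussian tails, no preferential sampling).

## Numerical choices

* Covariance factorizations attempt a plain Cholesky first; a
  $10^{-8}$ diagonal jitter (escalating ×100 up to a hard failure) is
  applied only on failure, so well-conditioned problems match dense
  reference computations exactly. The generator's multivariate draws
  always use the $10^{-8}$ jitter.
* $\omega^2 < 10^{-12}$ makes the individual-level covariance singular
  and is reported as an error (the boundary is approachable via the
  variance-ratio parameterization but not crossable).
* Raster convention, fixed for testability: cell-center registered,
  row-major from the top-left, half-open cells $[x_0, x_0+\Delta)$.
  Point extraction is nearest-cell lookup (covariates are "values of
  the containing grid cell"); interpolation happens only in
  `regrid_bilinear()`, which clamps beyond edge centers and therefore
  never overshoots the source range.
* Missing covariate rows are excluded from fitting with a logged count;
  masked prediction cells propagate `NA` and are counted.
* All file writes are atomic (write-temp-rename); outputs are plain
  text (CSV, ESRI ASCII grid, GeoJSON, JSON).

## Known limitations

* Exponential correlation only (no general Matérn, no anisotropy), by
  design.
* The ML estimate of the range $\phi$ carries the usual small negative
  finite-sample bias of spatial range parameters (on the order of a few
  percent at 300 clusters); the recovery suite quantifies it. REML-type
  corrections are not implemented.
* Exact-lag identification by AIC is intrinsically hard at small effect
  sizes: a per-SD effect with a t-statistic near 3 must out-fit eleven
  correlated competitor lags, so the scan recovers the exact lag in
  roughly two-thirds to four-fifths of survey-scale replicates (the
  acceptance suite measures this); neighbouring lags absorb the rest.
  Treat a selected lag as an estimate with uncertainty of about
  ±1–2 months, not an oracle.
* Plug-in prediction understates uncertainty when $\phi$ is weakly
  identified — inspect `profile_phi()` before trusting kriging SDs.
* District aggregation by cell centers can misassign boundary cells at
  coarse grid resolutions relative to polygon size.
* The pipeline's grid predictions use either a fixed reference birth
  month or the monthly climatology for lagged covariates; per-month
  prevalence surfaces require calling `predict()` per month.
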