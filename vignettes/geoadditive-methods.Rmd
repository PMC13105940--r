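---
title: "Methods: Bayesian geoadditive modelling of child weight-for-age"
author: "geowaz"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian geoadditive modelling of child weight-for-age}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geowaz)
```

## The model

`geowaz` fits a structured additive Gaussian regression for a continuous
anthropometric outcome, here the weight-for-age z-score (WAZ) of children
under five. For child $i$ with metrical covariates $x_{i1},\dots,x_{ip}$,
categorical covariates $w_i$, and region $s_i$,

$$
y_i = \sum_{j=1}^p f_j(x_{ij}) + f_{\mathrm{spat}}(s_i) + w_i'\gamma
      + \varepsilon_i,
\qquad \varepsilon_i \sim N(0, \sigma^2),
$$

with three kinds of terms:

* **P-spline smooths** $f_j$. Each metrical covariate (child age in
  months, maternal age in years, maternal BMI in kg/m²) enters through a
  B-spline basis on equidistant knots spanning the observed range,
  extended by `degree` knots on each side so every basis row is a
  partition of unity. The coefficient vector $\beta_j$ carries the
  improper Gaussian prior $p(\beta_j \mid \tau_j^2) \propto
  \exp\{-\beta_j' K_j \beta_j / 2\tau_j^2\}$ with $K_j = D_d' D_d$ the
  $d$-th order difference penalty — equivalently a random walk of order
  $d$ on adjacent coefficients. $K_j$ has rank $m_j - d$; its null space
  (polynomials of degree $d-1$) is unpenalized.
* **Intrinsic MRF spatial effect.** The region effect vector carries the
  intrinsic (pairwise-difference) Gaussian Markov random field prior with
  precision $K_{\mathrm{spat}}$ built from the region adjacency graph:
  diagonal entries are neighbour counts, off-diagonals $-1$ for adjacent
  pairs. Rows sum to zero and the rank is $S$ minus the number of graph
  components, so the prior penalizes differences between neighbouring
  regions and is indifferent to component-wise level shifts. The spatial
  term is the model's proxy for unobserved, geographically structured
  determinants.
* **Fixed effects** $\gamma$ with flat priors, dummy-coded against each
  factor's reference level (the first factor level; the synthetic
  generator emits reference levels first).

All smoothing variances $\tau_j^2$ (one per penalized block, including the
spatial term) and the error variance $\sigma^2$ have conjugate
inverse-gamma hyperpriors, $IG(a, b)$ with $a = b = 0.001$ by default —
the conventional weakly informative choice for variance parameters in this
model family. Shapes/scales are configurable globally and per term
(`prior_control()`).

### Assumptions

The response is Gaussian with a common variance across observations;
the additive predictor is correct (no interactions or varying
coefficients); observations are conditionally independent given the
predictor — the sampling design's cluster structure is represented only
through the spatial term, not through design weights. A histogram/KDE
check of the response (`density_profile()`) supports the Gaussian choice
on data like these; for strongly skewed outcomes the model is
misspecified and the diagnostics below should reveal it.

## Gibbs sampler

All full conditionals are conjugate, so the sampler is a systematic-scan
Gibbs cycle:

1. $\gamma \mid \cdot \sim N(\hat\gamma, \sigma^2 (W'W)^{-1})$ with
   $\hat\gamma$ the least-squares fit to the partial residual;
2. for each penalized block, $\beta_j \mid \cdot \sim N(\mu_j, \Sigma_j)$
   with $\Sigma_j^{-1} = B_j'B_j/\sigma^2 + K_j/\tau_j^2$ and
   $\mu_j = \Sigma_j B_j' r_j / \sigma^2$, drawn via a Cholesky
   factorization of the (small, $m_j \times m_j$) precision;
3. $\tau_j^2 \mid \cdot \sim IG(a + \mathrm{rank}(K_j)/2,\;
   b + \beta_j' K_j \beta_j / 2)$;
4. $\sigma^2 \mid \cdot \sim IG(a_\sigma + n/2,\; b_\sigma + \sum r_i^2/2)$.

**Identifiability and centring.** The intrinsic priors leave each smooth's
level and the spatial level unidentified against the intercept. After each
block update, a smooth's fitted values are recentred to mean zero over the
observations — implemented as a constant shift of the coefficients, exact
because basis rows sum to one — and the spatial effect is recentred to mean
zero over regions; the removed constant is added to the intercept, so the
linear predictor is unchanged. This is why retained draws of every smooth
have per-draw mean-zero fitted values and region effects average to zero,
while the overall WAZ level lives in the intercept.

**Initialisation and run lengths.** Fixed effects start at their OLS fit,
smooth and spatial blocks at zero, all variances at 0.1 — a deterministic,
fast-burning start. Defaults are 12,000 iterations, 2,000 burn-in,
thinning 10 (1,000 retained draws), single chain; all configurable via
`mcmc_control()`. One master seed drives a single RNG stream, so a run is
bit-reproducible given its seed; the low retained-draw autocorrelation can
be confirmed with `max_autocorrelation()`.

**Numerical safeguards.** The spatial full-conditional precision is
positive definite whenever every region is observed; if a factorization
nevertheless fails (e.g. unobserved regions), a $10^{-8}$ ridge is added
once and logged. A standalone `sample_coefficient_block()` call on a truly
singular precision raises an error advising the ridge rather than silently
regularizing. Negative penalty quadratic forms (numerically possible at
machine precision) are clamped to zero with a warning. Divergent
error-variance draws abort with the iteration and residual sum of squares
in the message.

## Defaults for the smooth terms

The P-spline defaults are cubic splines (`degree = 3`), 20 interior knots,
and a second-order difference penalty — the conventional defaults of the
structured-additive-regression software family this package follows; all
three are per-term configurable. Twenty interior knots give 24 basis
functions per smooth, ample for curves like the child-age profile while
the penalty carries the smoothing. Knots are equidistant on the observed
covariate range, so bases built on training data evaluate consistently on
new grids (`smooth_effects()` re-evaluates the stored knot vector).

## Summaries, significance and DIC

Posterior tables report the empirical mean, SD, and 2.5/50/97.5% quantiles
per parameter (linear interpolation of order statistics, R's default
type 7 — the package documents this convention since quantile definitions
differ). A parameter is **significant** when its equal-tailed 95% interval
excludes zero: "positive" when the 2.5% quantile is above zero, "negative"
when the 97.5% quantile is below. The 80% level appears only as inner
bands on smooth-effect curves, never for significance calls. The
smoothing-variance table additionally reports the minimum and maximum
across retained draws — an interpretation choice for that conventional
layout, documented here because "min/max" can also be read as posterior
range estimates, which these are not.

DIC uses the Gaussian deviance $D(\theta) = n\log(2\pi\sigma^2) +
\sum_i (y_i - \eta_i)^2/\sigma^2$, with $\bar D$ the mean over retained
draws and $D(\bar\theta)$ evaluated at the posterior-mean predictor and
posterior-mean $\sigma^2$; $p_D = \bar D - D(\bar\theta)$ and
$\mathrm{DIC} = \bar D + p_D$. $p_D$ can be negative under severe
non-normality of the posterior; it is reported as-is with a warning rather
than clamped, since a clamp would silently distort model comparison.

`stepwise_select()` is a greedy forward-backward search minimizing DIC
over candidate terms, with the full audit trail returned. DIC values carry
Monte-Carlo noise, so ties (and exact equalities on removal) resolve
toward the smaller model; each visited model gets a deterministic seed
derived from the master seed, making the whole search reproducible.

## Screening and mapping conventions

* **Yeo-Johnson screening** (`yeo_johnson()`, `fit_yeo_johnson()`,
  `binned_profile()`): the four-branch power transform defined for
  negative values, with $\lambda$ chosen by Gaussian profile likelihood
  over a coarse grid on $[-3, 3]$ plus golden-section refinement — bounds
  that cover standard practice; deterministic by construction. Binned
  covariate–response profiles default to 30 equal-width, right-closed
  bins (lowest bin closed), with empty bins emitted at count zero. The
  transform can be applied to the covariate, the response, or both — the
  screening display is visual, so both modes are supported.
* **IDW hotspot interpolation** (`idw_interpolate()`,
  `hotspot_classify()`): inverse-distance weights $d^{-p}$ with great-
  circle (haversine) distances in km and default power $p = 2$ (the
  common mapping default; configurable). A grid point coinciding with a
  source returns the source value exactly. What is interpolated is the
  cluster-level posterior-mean predicted WAZ with the sign flipped
  (`predict_severity_sources()`), so larger surface values mean worse
  predicted underweight; region-centroid sources are available as an
  alternative since cluster- vs. centroid-level interpolation is a
  genuine modelling choice. Hotspots are grid cells strictly above the
  80th percentile of the interpolated surface — a mapping convention
  (worst quintile), not an epidemiological threshold, and configurable.

## The synthetic-data generator

Real DHS child micro-data are access-restricted, so the package's testbed
is `simulate_underweight()`. Its defaults emulate the structure of the
2016 Ethiopian survey sample: 10,641 children across 11 regions and ~59
clusters per region; child age uniform on 0–59 months; maternal age
truncated-normal(28, 7) on 15–49 years; maternal BMI
truncated-normal(21, 3.5) on 12–50 kg/m²; rural share 81.45%; maternal
education shares 64.27/25.17/6.90/3.67%; diarrhoea-positive share 82.94%
(as the source survey summary reports it); anaemia and remaining binary
shares set to values typical of such surveys (43% not anaemic, 5% severe,
28% moderate, 24% mild; 70% without electricity; 25% female household
heads). True fixed effects default to the posterior means reported for
this model family on the real data (e.g. +0.0837 for female children,
−0.1976 for no electricity), the error SD to $\sqrt{1.3511} \approx 1.16$.

True smooth curves are closed forms matching the reported shapes: child
age declining steeply to ~10 months and plateauing by ~30
($-(1-e^{-t/8})$); maternal BMI an inverted U peaking at BMI 23 (Gaussian
bump, SD 5); maternal age flat to 35 then declining (softplus knee at 35).
Each is centred under its covariate distribution and scaled to SD 0.35 on
the response scale — about 0.3 error SDs, chosen once so each effect
explains a visible variance share and recovery is testable at n = 2,000.
True spatial effects are drawn from the intrinsic MRF prior itself via the
spectral decomposition of $K_{\mathrm{spat}}$ with null-space components
set to zero (so effects sum to zero exactly per graph component), scaled
by the spatial SD 0.55 (squaring to ≈ 0.30, the scale of the reported
spatial variance). Cluster coordinates are placed uniformly inside
per-region tiles of an Ethiopia-like bounding box (33–48°E, 3–15°N);
regions default to a rook lattice when no real adjacency is supplied.

What the generator does **not** emulate: DHS sampling weights and
non-response, anthropometric measurement error, within-cluster outcome
correlation beyond the region effect, covariate dependence (covariates are
drawn independently), and real region geometries. Passing recovery tests
on this testbed therefore demonstrates the estimator's correctness under
its own assumptions — not robustness to the design features of real survey
data.

## Test problem sizes

The statistical acceptance tests run at sizes chosen to make Monte-Carlo
error budgets explicit: conjugate-oracle comparison at n = 500 with 20,000
retained draws (batch-means standard errors, 3-SE bands; 4 SEs for
covariance entries); block-sampler oracle at 50,000 independent draws;
inverse-gamma conditional at 10,000 draws with a Kolmogorov–Smirnov check;
smooth/spatial recovery over 20 replicates at n = 2,000 (1,200 iterations
each); selection behaviour over 20 null replicates at n = 1,000; and a
single survey-scale (n = 10,641) fit for output-layout checks. The
survey-scale acceptance script uses 3,000 iterations with 1,000 burn-in
and thinning 2 — enough for stable posterior means at this n while keeping
the run to minutes.

## Known limitations

Gaussian response only (a binary underweight indicator would need a
latent-variable or Metropolis step); no tensor-product or
varying-coefficient smooths; no sampling weights; single-chain defaults
(multi-chain convergence checks can be run by varying the seed); DIC is
the only model-comparison criterion; IDW is a deterministic interpolator —
it reproduces no uncertainty surface and should not be read as a
geostatistical model.
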