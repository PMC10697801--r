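---
title: "Models and methods in reefherb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in reefherb}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`reefherb` models coral-reef herbivore biomass and benthic condition from
compiled underwater-survey data and gridded driver layers, and derives a
fishing-depletion threshold below which benthic condition is predicted to
decline. This vignette is the package's own account of the science: the
models and their assumptions, the tunable parameters, what the synthetic
data generator does and does not emulate, the numerical choices, and the
design decisions taken where the methodology was genuinely open.

## From raw surveys to replicates

Multi-institution survey compilations are heterogeneous, so the survey
module applies a fixed sequence of standardizations:

* **Calibration.** Counts are multiplied by species-by-method factors that
  reconcile survey methods. The factors are consumed as a lookup table;
  missing species/method pairs default to 1 with a warning rather than an
  error, because calibration tables are rarely complete.
* **Allometric biomass.** Weight is `a·TL^b` (g, TL in cm); density is
  `count · a · TL^b / area` in g m⁻². Species missing from the parameter
  table are an error, never a silent drop — silent drops bias biomass low.
* **Schooling truncation.** Occasional huge schools dominate survey-level
  biomass. Observations above the 99.9% quantile of all counts are flagged;
  for flagged herbivore species every count above the 99% quantile is set to
  the 99% quantile. Both quantiles use the sort-based (type 7) rule shared by
  all quantile computations in the package. The two-stage rule (flag wide,
  truncate narrower) never increases a count and is idempotent on tables
  large enough that the truncation plateau spans the flagging quantile.
* **Domain filter.** Hard bottom, 0–30 m, 2004–2014 — reef habitat in the
  decade preceding the 2014–2015 bleaching, so the models describe reefs
  before that pulse disturbance.
* **Replicates.** The analysis row is the *replicate*: surveys sharing
  source, latitude, longitude (rounded to 5 decimals, configurable, since
  sources record differing precision), depth and year, averaged over member
  transects with equal weight. Heavily monitored sites can be thinned to one
  year (`subsample_site`, by label or a 2.5 km radius rule), and moku with
  fewer than 5 replicates are dropped so spatial random effects are
  estimated from adequately sampled areas.
* **Benthic condition** is `log((coral + cca + δ) / (macroalgae + δ))` with
  floor `δ = 0.1`% cover. The floor keeps the statistic defined at zero
  cover and is symmetric, so the statistic remains antisymmetric under
  swapping calcified and macroalgal cover; it cancels whenever both sides
  are equal. δ is configurable because no convention exists for zeros in
  cover log-ratios.

## The hierarchical models

Both models share a linear predictor
`μ = ε_year + ε_dataset + ε_moku + β̄X` with independent
Normal(0, σ²_group) random effects under a **sum-to-zero constraint**: only
the first L−1 levels are sampled and the last is minus their sum. This keeps
the hierarchical effects identifiable against the intercept (the classic
near-nonidentifiability when effect variance is large relative to sample
variance) and is asserted exactly, in every retained draw, by the test
suite.

**Gamma biomass model.** `y ~ Gamma(shape κ, rate κ·e^{−μ})`, i.e. mean
`e^μ` — the mean-parameterized reading. A literal shape/rate reading of the
dispersion-times-exponential notation would give mean `e^{−μ}` and invert
every coefficient sign, contradicting the ecological interpretation
(fishing coefficients negative = less biomass), so the mean parameterization
is used and the generator mirrors it. Priors: `κ ~ Uniform(0, 100)`;
`β̄ ~ Normal(0, variance 100)` — with standardized predictors this is weakly
informative; a precision-100 reading would be strongly informative and is
rejected. Hierarchical SDs get Half-Normal(0, 2) priors on the log-predictor
scale: proper, weakly informative, and stable when a hierarchy has few
levels.

**Normal benthic model.** Response is the condition log-ratio;
`τ ~ Gamma(0.1, 0.1)` on the precision with `σ = τ^{−1/2}` (a reciprocal
reading `σ = 1/τ` is exposed in the prior config but is dimensionally odd
and off by default). Predictors are the centered `log(1+x)` biomasses of
grazers, scrapers and browsers, their three pairwise products and the triple
product (7 herbivore columns), plus standardized oceanography, pollution,
depth and rugosity. Fishing drivers are excluded — fishing is hypothesized
to act on the benthos through herbivores — and habitat classes are excluded
as circular with benthic cover. Interactions are formed *after* transforming
and centering: centering reduces the collinearity between main effects and
products, and the centering constants are stored in the design metadata and
reused verbatim at prediction time.

## Posterior computation

The sampling contract is the posterior law, the schedule (3 chains × 7500
iterations: 500 initialization, 2000 burn-in, 5000 retained) and the
diagnostics; the sampler itself is an implementation choice. `reefherb` uses
a Laplace-initialized blocked Metropolis–Hastings scheme:

1. The posterior mode and curvature are found by BFGS on an unconstrained
   parameterization (dispersion and hierarchical SDs on the log scale).
   Crucially, the mode search runs over the *location block only*
   (coefficients, sum-to-zero effects, dispersion) with the hierarchical SDs
   held fixed: the joint mode degenerates down the variance funnel
   (sd → 0 when effects are near zero), where a full Hessian is singular.
2. Each iteration updates the location block with a mixture kernel: with
   probability 0.85 an independence proposal from a multivariate t (df 10)
   centred at the mode with the Laplace covariance — GLM posteriors at these
   sample sizes are near-Gaussian, so this accepts often (≈ 0.3 observed)
   and mixes almost independently — otherwise a random-walk t step scaled by
   2.38/√d as a safeguard where the Laplace proposal is locally poor.
3. Each hierarchical log-SD is then updated by exact univariate slice
   sampling from its conditional, which involves only the few effect values,
   not the data, so the skewed small-level-count posteriors (where the
   Laplace approximation is worst) are handled exactly and cheaply.

All kernels are fixed — no adaptation — so the chain is a valid
time-homogeneous MCMC. Chains start overdispersed around the mode, and chain
`c` of a fit with seed `s` uses RNG seed `s + 7919·c`, making every fit
bit-reproducible. The test suite cross-checks the sampler against an
independent JAGS implementation of the same posterior on a small fixture;
posterior means agree within a fraction of a posterior SD.

Diagnostics: per-parameter Gelman–Rubin statistics computed directly from
the published formula `sqrt(((n−1)/n·W + B/n)/W)` (computed in-package so
degenerate cases — identical chains, constant parameters such as
single-level effects — stay well defined), with 1.1 as the flagging
threshold; posterior predictive checks on the mean and SD of replicated
responses; and Bayesian R² (`Var(fit)/(Var(fit)+Var(res))` per draw, with
`Var(res) = mean(fit²)/κ` for the gamma family). The reduced `"ci"` schedule
(3 × 1000 iterations) reproduces full-schedule point estimates within
Monte-Carlo error and is used throughout the validation suite.

**Leverage re-runs.** A coefficient driven by one anomalous cluster (e.g. a
single heavily monitored no-take area with high effluent values) can be
probed by zeroing the flagged observations' native driver values (before
standardization), rebuilding the design and refitting; the report states
whether the 95% interval contains zero before and after.

## Counterfactual prediction and the depletion threshold

Per pixel, *expected* biomass uses measured drivers; *potential* biomass
sets the fishing drivers to native zero before standardization and leaves
everything else unchanged. The ratio is computed on **matched posterior
draws** (same draw index in numerator and denominator), which the
ratio-of-posteriors construction implies — mismatched pairing would inflate
the ratio variance. Grid predictions set year and dataset effects to zero
(their sum-to-zero mean — a "typical year and source" map) and use the
fitted moku effect; pixels in unseen moku either error or fall back to the
population level, by configuration. Two identities pin the arithmetic down:
pixels with natively zero fishing return exactly 100%, and the draw-wise
ratio equals the closed form `exp(Σ β_j Δx_j)` to 1e−10.

The benthic counterfactual evaluates the benthic linear predictor (no
observation noise — the comparison is of condition, not single-survey
outcomes) under the posterior-mean functional-group biomasses of each
scenario. A pixel is *affected* when the 25th percentile of the potential
posterior exceeds the 75th percentile of the expected posterior. The
threshold is solved by exact logit inversion of the fitted logistic curve at
probability 0.99, not by grid search; complete separation is detected and
reported with the mid-gap threshold, and a Wald slope interval containing
zero flags the threshold as unreliable. Pixels with non-finite % potential
are excluded and reported.

## Post-stratification

Survey compilations are not spatially balanced, so area summaries pool the
full posterior draws of every 100 m hard-bottom pixel in an area with equal
weight — one pixel, one vote — and report the pooled mean and central 50%
interval (sort-based quantiles, the same rule as the classification). Areas
are ranked into rank-balanced quartiles, and against a reference posterior
(e.g. pooled no-take reserves) an area is "lower than reference" only when
its 50% interval lies entirely below the reference's.

## Management hurdle analysis

Management effects on parrotfish biomass combine a binomial presence model
and a gamma model of positive biomass, both single-factor GLMs, with
combined prediction `p̂ · E[y | y>0]` per level — an identity that holds
exactly for every bootstrap resample because the single-factor MLE equals
the per-level presence fraction and positive mean. Wald z (binomial) and t
(gamma) statistics are reported with residual degrees of freedom. The
bootstrap is stratified by management level: unstratified resampling can
empty a level, which would break the design, and the stratification
preserves the per-level sample sizes. Resamples in which a level loses all
positive observations are discarded and counted. Intervals are
bias-corrected (BC) percentile intervals
(`Φ(2z₀ ± z_{α/2})` quantiles of the bootstrap distribution with
`z₀ = Φ⁻¹(P(t* < t̂))`); the acceleration-corrected BCa variant is not
implemented — with single-factor group statistics the bias correction is the
dominant adjustment, and BC is the package's single, documented convention.
When a dataset contains no zeros the analysis degrades to a gamma-only
model, which coincides with the hurdle model at presence 1.

## The synthetic-data generator

The generator is the package's ground truth. It emulates the *structure* of
the real analysis inputs: 27 drivers in four groups drawn from a
block-structured Gaussian copula (within-group correlation by default 0.3,
across groups 0.09) and mapped to native units — fishing pressures
non-negative with exact zeros on a contiguous "remote" 5% of the coastline,
pollution lognormal, oceanography affine, depth clipped to 0.5–30 m; moku as
contiguous pixel blocks so post-stratification sees within-area driver
heterogeneity; survey replicates over years × datasets × moku with
sum-to-zero hierarchical effects drawn at SDs 0.10 / 0.30 / 0.15
(year / moku / dataset) and gamma biomass with shape κ = 4 around a 30 g m⁻²
baseline — magnitudes chosen once as representative of reef-fish survey
dispersion; a Dirichlet functional-group split (concentration 50 around
proportions 0.45 / 0.30 / 0.15 / 0.10); a benthic log-ratio generated from
the same centered-log1p herbivore block the model fits, converted to
consistent coral/CCA/macroalgae covers; raw fish records decomposed from
replicate biomass via the built-in (synthetic) species table, with
multiplicative count spikes on schooling species to exercise the truncation
rule; and zero-inflated management strata for the hurdle module. RNG streams
are split per table, so generating the fish records never perturbs the
replicate table, and every generator is bit-reproducible from its seed.

What it does **not** emulate: spatial autocorrelation beyond moku blocks,
real Hawaiʻi geography or bathymetry, species-level abundance structure,
observation error in benthic cover, or temporal trends. Passing tests
therefore demonstrate that the estimators recover the generating process
under correct model specification at realistic noise levels — not that the
models are robust to the misspecifications real reef data contain.

## Validation design and problem sizes

The test suite validates each operation against independent oracles
(sort-based quantile reimplementations, closed-form ratios, method-of-moments
estimates, brute-force grouping, JAGS) and runs four simulation studies,
with sizes chosen to give stable Monte-Carlo behaviour at desk scale:
coefficient recovery (20 seeds × n = 2000 replicates, 5 drivers, 3 years /
4 moku / 2 datasets; ≥ 90% empirical coverage of 95% intervals), end-to-end
threshold recovery (10 seeds × 250 pixels × 800 replicates), hurdle interval
calibration (50 seeds × B = 500; true fold-change 2.0 covered ≥ 90%), and
pipeline determinism (identical config + seed ⇒ identical artifact
checksums). For the threshold study the *analytically implied* threshold is
derived from the generating parameters: per pixel, the depletion ratio at
which the true benthic shift `Σ b_g·(log1p(B_g) − log1p(r·B_g))` equals that
pixel's posterior IQR (the classification boundary), with the
99%-probability threshold taken as the 99th percentile of the per-pixel
thresholds — the probability level reflects the most sensitive pixels, not
the median pixel. The recovered threshold agrees with this value to within
about 1.5 percentage points on average.

## Known limitations

* The sampler's independence proposal is tuned for the log-concave GLM
  posteriors fitted here; strongly multimodal posteriors would need a
  different backend (the module contract deliberately fixes only the
  posterior law, schedule and diagnostics).
* Bayesian R² for the gamma family uses the model-based residual variance
  `mean(fit²)/κ`, which understates residual dispersion if the gamma family
  is misspecified.
* `subsample_site`'s radius rule uses haversine distance on coordinates; no
  projection handling beyond that.
* Area summaries weight pixels equally; no partial-pixel or area-size
  reweighting.
* GeoTIFF export of grids and counterfactual maps is out of scope; all
  artifacts are CSV/JSON/YAML.
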