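# reefherb

Hierarchical Bayesian analysis of coral-reef herbivore biomass, benthic
condition, and fishing-depletion thresholds.

## The problem

Herbivorous reef fishes (grazers such as surgeonfishes, scraper/excavators
such as parrotfishes, browsers such as chubs) keep algae in check and help
maintain reefs in a calcified, coral-dominated state. Managers need to know
(i) which human and biophysical drivers shape herbivore biomass, (ii) how
benthic condition responds to herbivore functional groups, (iii) how much
fishing-driven depletion the benthos tolerates before condition declines, and
(iv) whether fisheries interventions actually rebuild herbivore populations.
`reefherb` implements a complete, tested pipeline for these questions,
designed for multi-institution underwater-survey compilations combined with
gridded (100 m) driver layers, and ships a synthetic-data generator with
known ground truth so every stage can be validated end to end.

## The models

**Herbivore biomass** (one model per metric: total, grazer, scraper, browser
biomass in g m⁻²), a hierarchical gamma GLM with log link:

    y_imyd ~ Gamma(shape = κ, mean = exp(μ_imyd))
    μ_imyd = ε_y + ε_d + ε_m + β̄ X
    κ ~ Uniform(0, 100),  β̄ ~ Normal(0, 10²)

where `X` are standardized drivers in four groups (fishing, land-based
pollution, oceanography, habitat) plus habitat-class indicators, and
`ε_y, ε_d, ε_m` are year, dataset and moku (land-division) random effects
under a sum-to-zero constraint (the last level equals minus the sum of the
others, so each effect vector sums to zero in every posterior draw).

**Benthic condition**, the log-ratio of calcified (coral + crustose
coralline algae) to macroalgal cover, a hierarchical normal model whose
predictors are the log(1+x)-transformed, centered biomasses of the three
herbivore functional groups with all two- and three-way interactions, plus
oceanography, pollution, depth and rugosity (no fishing terms — fishing acts
through herbivores; no habitat classes — circular with the response):

    y ~ Normal(μ, σ),  τ = 1/σ² ~ Gamma(0.1, 0.1)

**Counterfactual threshold.** For every grid pixel the fitted herbivore
models give matched posterior draws of *expected* biomass (measured drivers)
and *potential* biomass (fishing drivers at native zero), hence
`% potential = 100 · expected / potential`. The benthic model is evaluated
under both scenarios; a pixel is *affected* when the 25th percentile of its
benthic posterior under potential biomass exceeds the 75th percentile under
expected biomass. A logistic regression of unaffected(1)/affected(0) on
median % potential, inverted at probability 0.99, yields the depletion
threshold `x*`.

**Management effects** on parrotfish biomass use a binomial–gamma hurdle
model (presence ~ management with logit link; positive biomass ~ management
with log link), combined prediction = presence probability × conditional
mean, with stratified nonparametric bootstrap and bias-corrected (BC)
percentile intervals.

Posterior sampling uses a Laplace-initialized blocked Metropolis–Hastings
sampler (independence + random-walk mixture for location parameters, exact
univariate slice updates for hierarchical SDs), with 3 chains of 7500
iterations (500 initialization, 2000 burn-in, 5000 retained) by default and
a reduced `"ci"` schedule for fast validation; convergence is monitored with
Gelman–Rubin statistics, posterior predictive checks and Bayesian R².

## Worked example

```r
library(reefherb)

grid  <- make_driver_grid(n_pixels = 400, n_moku = 4, seed = 1)
truth <- make_truth(list(
  beta = c(fishing_noncomm_boat_spear = -0.35, fishing_noncomm_boat_net = -0.25,
           habitat_rugosity = 0.2)))
sim  <- simulate_surveys(grid, truth, n_replicates = 1200, seed = 2)
reps <- drop_sparse_moku(filter_domain(sim$replicates))

drivers <- c("fishing_noncomm_boat_spear", "fishing_noncomm_boat_net",
             "ocean_wave_anom_max", "habitat_rugosity", "habitat_depth")
std  <- standardize_drivers(reps, drivers)
spec <- hier_spec(
  response   = "biomass_total",
  design_fun = function(d) build_design(d, drivers, std$params, "herbivore"),
  family     = "gamma-log", mcmc = mcmc_schedule("ci"), seed = 3)
fit <- fit_gamma_glm(spec, reps)
fit
#> Hierarchical Bayesian gamma-log model: 1950 draws (3 chains), 1046 obs
#>   max Gelman-Rubin: 1.019 | median Bayes R2: 0.477
#>                    parameter        group       median          l50          u50
#> 1                (Intercept)    intercept  3.406137970  3.386723353  3.430145750
#> 2 fishing_noncomm_boat_spear      fishing -0.345061662 -0.356014387 -0.334017108
#> 3   fishing_noncomm_boat_net      fishing -0.283916090 -0.295779080 -0.270693729
#> 4        ocean_wave_anom_max oceanography -0.007467905 -0.017953304  0.003691928
#> 5           habitat_rugosity      habitat  0.175254224  0.164336515  0.185967274
#> ...
```

The posterior medians recover the generating coefficients (−0.35, −0.25,
0, +0.2, 0): spearfishing and net fishing deplete herbivore biomass, rugosity
enhances it. Counterfactual prediction and post-stratification then
summarize fishing depletion per pixel and per moku:

```r
cf <- predict_counterfactual(fit, mask_softbottom(grid), max_draws = 300)
summary(cf$median_percent)
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>   0.437  54.326  69.939  66.342  80.858 100.000

rank_areas(poststratify_area(cf$expected, cf$moku_id))
#>   area_id     mean      l50      u50 n_pixels quartile
#> 1 moku_01 49.93861 39.08862 56.08097       86        4
#> 2 moku_02 23.59048 19.89256 27.05211       89        1
#> 3 moku_03 32.01157 25.75121 38.46431       89        2
#> 4 moku_04 32.99720 26.90110 38.80504       80        3
```

Median % potential biomass spans 0.4–100% across pixels (remote pixels with
no fishing sit exactly at 100), and moku_01 — the block with the least
fishing pressure in this simulation — ranks in the top biomass quartile.
`run_pipeline()` drives the full chain (simulate → prep → herbivore and
benthic fits → threshold → post-stratification → hurdle → report) from a
single config list or YAML file and writes per-stage artifacts with a hash
manifest.

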