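# shared fixtures built in code

tiny_species <- function() {
  data.frame(
    species_code = c("PARROT", "CHUB", "TANG", "JACK"),
    a = c(0.0135, 0.02, 0.025, 0.017),
    b = c(3.05, 3.0, 2.95, 3.0),
    functional_group = c("scraper", "browser", "grazer", "other"),
    herbivore = c(TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
}

tiny_allometric <- function(calibration = NULL) {
  allometric_table(tiny_species(), calibration)
}

# small world: grid + truth with known driver effects
small_world <- function(seed = 1, n_pixels = 200, n_moku = 4,
                        beta = c(fishing_noncomm_boat_spear = -0.4,
                                 habitat_rugosity = 0.2)) {
  grid <- make_driver_grid(n_pixels, n_moku, seed = seed)
  truth <- make_truth(list(beta = beta, seed = seed))
  list(grid = grid, truth = truth)
}

# a quick reduced-schedule gamma fit on a small simulated dataset, reused by
# several test files (memoised per session)
cached_gamma_fit <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    w <- small_world(seed = 42, n_pixels = 250)
    sim <- simulate_surveys(w$grid, w$truth, 700, seed = 43)
    reps <- sim$replicates
    drivers <- c("fishing_noncomm_boat_spear", "fishing_noncomm_boat_net",
                 "ocean_wave_anom_max", "habitat_rugosity", "habitat_depth")
    std <- standardize_drivers(reps, drivers)
    spec <- hier_spec(
      "biomass_total",
      design_fun = function(d) build_design(d, drivers, std$params, "herbivore"),
      family = "gamma-log", mcmc = mcmc_schedule("ci"), seed = 5)
    cache <<- list(fit = fit_gamma_glm(spec, reps), reps = reps, spec = spec,
                   world = w, sim = sim, drivers = drivers, params = std$params)
    cache
  }
})

# sort-based quantile oracle: linear interpolation between order statistics
# (independent of stats::quantile)
oracle_q7 <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}
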