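# Synthetic-data generators: a driver grid, a ground-truth parameter object, survey
# replicates with raw fish records, and zero-inflated management-stratum datasets.
# Every downstream stage of the pipeline can be exercised against known truth.

#' Catalogue of the 27 synthetic reef drivers
#'
#' Returns the driver catalogue used by [make_driver_grid()]: 27 drivers in four
#' groups (7 fishing, 6 land-based pollution, 9 physical oceanography, 5 habitat),
#' mirroring the structure of gridded human/biophysical predictor stacks used in
#' reef condition analyses. `transform` controls how the latent correlated
#' Gaussian field is mapped to native units; fishing drivers are non-negative
#' with exact zeros on remote coastline segments.
#'
#' @return A data frame with columns `driver`, `group`, `transform`, `scale`,
#'   `center`.
#' @export
reef_driver_info <- function() {
  data.frame(
    driver = c(
      "fishing_comm_boat_net", "fishing_comm_boat_line", "fishing_comm_boat_spear",
      "fishing_noncomm_boat_net", "fishing_noncomm_boat_spear",
      "fishing_noncomm_shore_net", "fishing_noncomm_shore_spear",
      "pollution_urban_runoff", "pollution_ag_runoff", "pollution_osds_effluent",
      "pollution_sediment", "pollution_golf_runoff", "pollution_habitat_modification",
      "ocean_sst_mean", "ocean_sst_sd", "ocean_sst_max",
      "ocean_wave_anom_max", "ocean_wave_anom_freq", "ocean_irradiance_mean",
      "ocean_chla_mean", "ocean_chla_max", "ocean_chla_anom_freq",
      "habitat_depth", "habitat_rugosity", "habitat_slope",
      "habitat_patchiness", "habitat_reef_width"
    ),
    group = c(
      rep("fishing", 7L), rep("pollution", 6L), rep("oceanography", 9L),
      rep("habitat", 5L)
    ),
    transform = c(
      rep("lognormal_remote", 7L), rep("lognormal", 6L), rep("affine", 9L),
      "depth", "lognormal", "affine", "affine", "lognormal"
    ),
    scale = c(
      rep(1, 7L), rep(1, 6L),
      0.6, 0.25, 0.7, 0.8, 0.15, 40, 0.05, 0.08, 0.1,
      7, 0.3, 4, 2, 0.4
    ),
    center = c(
      rep(0, 13L),
      25.5, 0.8, 27.5, 2.5, 0.5, 300, 0.12, 0.25, 0.3,
      15, 0, 12, 6, 0
    ),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic 100 m driver grid
#'
#' Simulates `n_pixels` grid cells along a synthetic coastline with the 27
#' drivers of [reef_driver_info()], drawn from a block-structured Gaussian
#' copula (within-group correlation `correlation_level`, across groups
#' `0.3 * correlation_level`) and transformed to native units. Moku (land
#' divisions) are contiguous blocks of pixels, so post-stratification sees
#' within-area driver heterogeneity. A contiguous `remote_fraction` of the
#' coastline has all fishing drivers natively zero, emulating remote reefs.
#'
#' @param n_pixels Number of pixels (>= `n_moku`).
#' @param n_moku Number of contiguous moku blocks.
#' @param correlation_level Within-group latent correlation in `[0, 1)`.
#' @param seed Integer RNG seed; identical seeds give bit-identical grids.
#' @param remote_fraction Fraction of coastline with zero fishing pressure.
#' @param prop_softbottom Expected fraction of soft-bottom pixels.
#' @return A data frame of class `reef_grid` with `pixel_id`, `lon`, `lat`,
#'   the 27 driver columns, `moku_id`, `hardbottom_flag` and `habitat_class`;
#'   the driver catalogue is attached as attribute `driver_info`.
#' @export
make_driver_grid <- function(n_pixels, n_moku = 4L, correlation_level = 0.3,
                             seed = 1L, remote_fraction = 0.05,
                             prop_softbottom = 0.15) {
  n_pixels <- check_count(n_pixels, "n_pixels")
  n_moku <- check_count(n_moku, "n_moku")
  if (n_pixels < n_moku)
    stopf("invalid argument: n_pixels (%d) must be >= n_moku (%d)", n_pixels, n_moku)
  if (correlation_level < 0 || correlation_level >= 1)
    stopf("invalid argument: correlation_level must be in [0, 1)")
  info <- reef_driver_info()
  k <- nrow(info)
  set.seed(seed)

  # block covariance: within-group correlation_level, cross-group 0.3x
  same_group <- outer(info$group, info$group, "==")
  Sigma <- ifelse(same_group, correlation_level, 0.3 * correlation_level)
  diag(Sigma) <- 1
  Lc <- chol(Sigma)
  Z <- matrix(stats::rnorm(n_pixels * k), n_pixels, k) %*% Lc
  colnames(Z) <- info$driver

  remote <- rep(FALSE, n_pixels)
  n_remote <- floor(remote_fraction * n_pixels)
  if (n_remote > 0) remote[(n_pixels - n_remote + 1L):n_pixels] <- TRUE

  X <- matrix(NA_real_, n_pixels, k, dimnames = list(NULL, info$driver))
  for (j in seq_len(k)) {
    z <- Z[, j]
    X[, j] <- switch(info$transform[j],
      lognormal_remote = ifelse(remote, 0, exp(0.8 * z) * info$scale[j]),
      lognormal = exp(0.8 * z) * info$scale[j],
      affine = info$center[j] + info$scale[j] * z,
      depth = pmin(30, pmax(0.5, info$center[j] + info$scale[j] * z)),
      stopf("unknown transform '%s'", info$transform[j])
    )
  }

  moku_id <- sprintf("moku_%02d", ceiling(seq_len(n_pixels) / n_pixels * n_moku))
  grid <- data.frame(
    pixel_id = seq_len(n_pixels),
    lon = -156 + 0.0009 * (seq_len(n_pixels) - 1L),
    lat = 20.8 + 0.0002 * sin(seq_len(n_pixels) / 40),
    X,
    moku_id = moku_id,
    hardbottom_flag = stats::runif(n_pixels) > prop_softbottom,
    habitat_class = sample(c("reef", "pavement", "boulder", "other"), n_pixels,
                           replace = TRUE, prob = c(0.4, 0.25, 0.15, 0.2)),
    stringsAsFactors = FALSE
  )
  attr(grid, "driver_info") <- info
  class(grid) <- c("reef_grid", "data.frame")
  grid
}

default_benthic_beta <- function() {
  c(intercept = 0,
    grazer = 0.35, scraper = 0.45, browser = 0.25,
    `grazer:scraper` = -0.12, `grazer:browser` = -0.08, `scraper:browser` = -0.10,
    `grazer:scraper:browser` = 0.06)
}

#' Construct a synthetic ground-truth parameter object
#'
#' Builds the generative parameter set shared by [simulate_surveys()] and
#' [simulate_hurdle_case()]. Unspecified entries take documented defaults:
#' all driver coefficients zero, intercept `log(30)` (about 30 g m^-2 of
#' herbivore biomass), gamma shape `kappa = 4`, hierarchical SDs 0.10 / 0.30 /
#' 0.15 (year / moku / dataset, log scale), benthic herbivore effects with
#' positive main effects, negative two-way and positive three-way interactions,
#' and a two-level management hurdle (open vs protected).
#'
#' @param config Named list overriding any default field.
#' @return An object of class `reef_truth`.
#' @export
make_truth <- function(config = list()) {
  info <- reef_driver_info()
  beta <- c(intercept = log(30),
            stats::setNames(rep(0, nrow(info)), info$driver))
  defaults <- list(
    beta = beta,
    kappa = 4,
    sigma_year = 0.10,
    sigma_moku = 0.30,
    sigma_dataset = 0.15,
    benthic_beta = default_benthic_beta(),
    sigma_benthic = 0.8,
    fg_props = c(grazer = 0.45, scraper = 0.30, browser = 0.15, other = 0.10),
    fg_conc = 50,
    hurdle_p = c(open = 0.6, protected = 0.9),
    hurdle_mu = c(open = 10, protected = 25),
    hurdle_kappa = 2,
    seed = 1L
  )
  if (!is.list(config)) stopf("invalid argument: config must be a list")
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stopf("invalid argument: unknown truth field(s): %s", paste(unknown, collapse = ", "))
  truth <- utils::modifyList(defaults, config)
  # partial beta overrides by name merge into the full default vector
  if (!is.null(config$beta)) {
    b <- defaults$beta
    if (is.null(names(config$beta)))
      stopf("invalid argument: beta overrides must be named")
    bad <- setdiff(names(config$beta), names(b))
    if (length(bad))
      stopf("invalid argument: unknown beta name(s): %s", paste(bad, collapse = ", "))
    b[names(config$beta)] <- config$beta
    truth$beta <- b
  }
  if (!is.null(config$benthic_beta)) {
    bb <- defaults$benthic_beta
    extra <- setdiff(names(config$benthic_beta), names(bb))
    bb[names(config$benthic_beta)] <- config$benthic_beta
    truth$benthic_beta <- bb[c(names(defaults$benthic_beta), extra)]
  }
  validate_truth(truth)
  class(truth) <- "reef_truth"
  truth
}

validate_truth <- function(t) {
  if (!is.numeric(t$kappa) || t$kappa <= 0)
    stopf("invalid argument: kappa must be > 0")
  if (!is.numeric(t$hurdle_kappa) || t$hurdle_kappa <= 0)
    stopf("invalid argument: hurdle_kappa must be > 0")
  for (s in c("sigma_year", "sigma_moku", "sigma_dataset", "sigma_benthic"))
    if (!is.numeric(t[[s]]) || t[[s]] < 0)
      stopf("invalid argument: %s must be >= 0", s)
  if (any(t$hurdle_p < 0 | t$hurdle_p > 1))
    stopf("invalid argument: hurdle_p must lie in [0, 1]")
  if (is.null(names(t$hurdle_p)) || is.null(names(t$hurdle_mu)))
    stopf("invalid argument: hurdle_p and hurdle_mu must be named by level")
  if (!setequal(names(t$hurdle_p), names(t$hurdle_mu)))
    stopf("invalid argument: hurdle_p and hurdle_mu levels differ")
  if (any(t$hurdle_mu <= 0))
    stopf("invalid argument: hurdle_mu must be > 0")
  if (abs(sum(t$fg_props) - 1) > 1e-8)
    stopf("invalid argument: fg_props must sum to 1")
  invisible(t)
}

#' Serialize a truth object to a plain list
#'
#' The result round-trips through [make_truth()]: `make_truth(truth_to_list(t))`
#' equals `t`. Suitable for writing as YAML.
#'
#' @param truth A `reef_truth` object.
#' @return A named list of plain vectors.
#' @export
truth_to_list <- function(truth) {
  stopifnot(inherits(truth, "reef_truth"))
  unclass(truth)
}

#' Write / read a truth object as a YAML config file
#'
#' @param truth A `reef_truth` object.
#' @param path File path.
#' @return `read_truth()` returns a `reef_truth`; `write_truth()` the path,
#'   invisibly.
#' @export
write_truth <- function(truth, path) {
  l <- truth_to_list(truth)
  l <- lapply(l, function(x) if (!is.null(names(x))) as.list(x) else x)
  yaml::write_yaml(l, path, precision = 15L)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  l <- yaml::read_yaml(path)
  l <- lapply(l, function(x) if (is.list(x)) unlist(x) else x)
  make_truth(l)
}

# standardized design matrix for the grid's 27 drivers using grid-wide moments
grid_standardized <- function(grid, info = attr(grid, "driver_info")) {
  X <- as.matrix(grid[, info$driver, drop = FALSE])
  scale(X)
}

#' Simulate survey replicates and raw fish records from known truth
#'
#' Draws `n_replicates` survey replicates on pixels of `grid`. Total herbivore
#' biomass follows a gamma law with shape `truth$kappa` and mean
#' `exp(eps_year + eps_dataset + eps_moku + X beta)` on standardized drivers;
#' hierarchical effects are drawn under the sum-to-zero convention (the last
#' level equals minus the sum of the others, so each realized effect vector
#' sums to zero exactly). Functional-group biomasses are a Dirichlet split of
#' the total; a benthic condition log-ratio is drawn from a normal law on
#' centered `log(1 + biomass)` functional-group terms and their interactions,
#' and converted to consistent coral / CCA / macroalgae percent covers. Raw
#' fish records (species, length, count) are decomposed from replicate
#' biomass and are marginally consistent with it; a configurable fraction of
#' records of schooling species receives multiplicative count spikes.
#'
#' The RNG stream is split per table (replicates vs fish records): adding or
#' dropping the fish table does not perturb the replicate table.
#'
#' @param grid A `reef_grid`.
#' @param truth A `reef_truth`.
#' @param n_replicates,n_years,n_datasets Design sizes (`n_replicates` may be 0).
#' @param seed Integer RNG seed.
#' @param survey_area Transect area in m^2 used for the fish records.
#' @param school_fraction Probability a schooling-species record is spiked.
#' @param school_factor Multiplicative spike applied to such counts.
#' @return A list with `replicates` (one row per survey replicate), `fish`
#'   (raw observation records) and `effects` (the realized hierarchical
#'   effect vectors, for validation).
#' @export
simulate_surveys <- function(grid, truth, n_replicates, n_years = 3L,
                             n_datasets = 2L, seed = 1L, survey_area = 125,
                             school_fraction = 0.01, school_factor = 50) {
  stopifnot(inherits(grid, "reef_grid"), inherits(truth, "reef_truth"))
  if (nrow(grid) == 0L) stopf("invalid argument: grid is empty")
  n_replicates <- check_count(n_replicates, "n_replicates", min = 0L)
  n_years <- check_count(n_years, "n_years")
  n_datasets <- check_count(n_datasets, "n_datasets")
  info <- attr(grid, "driver_info")
  species <- reef_species_table()

  if (n_replicates == 0L) {
    return(list(replicates = empty_replicates(), fish = empty_fish(),
                effects = list(year = numeric(0), moku = numeric(0),
                               dataset = numeric(0))))
  }

  set.seed(seed)
  years <- 2004L + seq_len(n_years) - 1L
  datasets <- sprintf("ds_%02d", seq_len(n_datasets))
  moku_levels <- sort(unique(grid$moku_id))

  draw_effects <- function(n, s) {
    if (n == 1L) return(0)
    expand_sum_to_zero(stats::rnorm(n - 1L, 0, s), n)
  }
  eff <- list(
    year = stats::setNames(draw_effects(n_years, truth$sigma_year), as.character(years)),
    moku = stats::setNames(draw_effects(length(moku_levels), truth$sigma_moku), moku_levels),
    dataset = stats::setNames(draw_effects(n_datasets, truth$sigma_dataset), datasets)
  )

  pix <- sample.int(nrow(grid), n_replicates, replace = TRUE)
  year <- sample(years, n_replicates, replace = TRUE)
  dataset <- sample(datasets, n_replicates, replace = TRUE)
  Xs <- grid_standardized(grid, info)[pix, , drop = FALSE]
  beta <- truth$beta
  mu <- beta[["intercept"]] + as.vector(Xs %*% beta[info$driver]) +
    eff$year[as.character(year)] + eff$moku[grid$moku_id[pix]] +
    eff$dataset[dataset]
  biomass_total <- stats::rgamma(n_replicates, shape = truth$kappa,
                                 rate = truth$kappa / exp(mu))

  # Dirichlet split of total biomass into functional groups
  a <- truth$fg_props * truth$fg_conc
  G <- matrix(stats::rgamma(n_replicates * 4L, shape = rep(a, each = n_replicates)),
              n_replicates, 4L, dimnames = list(NULL, names(truth$fg_props)))
  G <- G / rowSums(G)
  fg <- G * biomass_total

  # benthic linear predictor on centered log1p functional-group biomass
  lg <- log1p(fg[, c("grazer", "scraper", "browser"), drop = FALSE])
  centers <- colMeans(lg)
  lgc <- sweep(lg, 2L, centers)
  bb <- truth$benthic_beta
  lp <- bb[["intercept"]] +
    bb[["grazer"]] * lgc[, "grazer"] + bb[["scraper"]] * lgc[, "scraper"] +
    bb[["browser"]] * lgc[, "browser"] +
    bb[["grazer:scraper"]] * lgc[, "grazer"] * lgc[, "scraper"] +
    bb[["grazer:browser"]] * lgc[, "grazer"] * lgc[, "browser"] +
    bb[["scraper:browser"]] * lgc[, "scraper"] * lgc[, "browser"] +
    bb[["grazer:scraper:browser"]] * lgc[, "grazer"] * lgc[, "scraper"] * lgc[, "browser"]
  extra <- intersect(names(bb), info$driver)
  for (dn in extra) lp <- lp + bb[[dn]] * Xs[, dn]
  benthic_logratio <- stats::rnorm(n_replicates, lp, truth$sigma_benthic)

  # covers consistent with the log-ratio: total benthos split by inverse-logit
  total_cover <- stats::runif(n_replicates, 20, 80)
  calcified <- total_cover * stats::plogis(benthic_logratio)
  macroalgae <- total_cover - calcified
  coral <- 0.75 * calcified
  cca <- 0.25 * calcified

  replicates <- data.frame(
    replicate_id = seq_len(n_replicates),
    source_dataset = dataset,
    latitude = grid$lat[pix],
    longitude = grid$lon[pix],
    depth_m = grid$habitat_depth[pix],
    year = year,
    pixel_id = grid$pixel_id[pix],
    moku_id = grid$moku_id[pix],
    habitat_class = grid$habitat_class[pix],
    hardbottom = grid$hardbottom_flag[pix],
    biomass_total = biomass_total,
    biomass_grazer = fg[, "grazer"],
    biomass_scraper = fg[, "scraper"],
    biomass_browser = fg[, "browser"],
    biomass_other = fg[, "other"],
    coral = coral, cca = cca, macroalgae = macroalgae,
    benthic_logratio = benthic_logratio,
    stringsAsFactors = FALSE
  )
  native <- grid[pix, info$driver, drop = FALSE]
  rownames(native) <- NULL
  replicates <- cbind(replicates, native)
  attr(replicates, "benthic_centers") <- centers
  attr(replicates, "mu") <- mu

  # fish records on an independent substream
  set.seed(seed + 1000003L)
  fish <- decompose_fish_records(replicates, species, truth$fg_props,
                                 survey_area, school_fraction, school_factor)
  list(replicates = replicates, fish = fish, effects = eff)
}

empty_replicates <- function() {
  data.frame(replicate_id = integer(0), source_dataset = character(0),
             latitude = numeric(0), longitude = numeric(0), depth_m = numeric(0),
             year = integer(0), biomass_total = numeric(0))
}

empty_fish <- function() {
  data.frame(transect_id = integer(0), species_code = character(0),
             count = numeric(0), total_length_cm = numeric(0),
             method = character(0))
}

decompose_fish_records <- function(replicates, species, fg_props, survey_area,
                                   school_fraction, school_factor) {
  recs <- vector("list", nrow(replicates))
  groups <- c("grazer", "scraper", "browser", "other")
  for (i in seq_len(nrow(replicates))) {
    out <- list()
    for (g in groups) {
      bg <- replicates[[paste0("biomass_", g)]][i]
      if (bg <= 0) next
      cand <- species[species$functional_group == g, , drop = FALSE]
      sp <- cand[sample.int(nrow(cand), 1L), , drop = FALSE]
      tl <- pmin(60, pmax(4, stats::rlnorm(1, log(sp$tl_typical), 0.25)))
      count <- round(bg * survey_area / (sp$a * tl^sp$b))
      if (count < 1) next
      if (sp$schooling && stats::runif(1) < school_fraction)
        count <- count * school_factor
      out[[g]] <- data.frame(
        transect_id = replicates$replicate_id[i],
        species_code = sp$species_code, count = count,
        total_length_cm = tl,
        method = ifelse(replicates$source_dataset[i] == "ds_01", "belt", "spc"),
        stringsAsFactors = FALSE
      )
    }
    recs[[i]] <- do.call(rbind, out)
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out %||% empty_fish()
}

#' Built-in synthetic species parameter table
#'
#' A small synthetic example of the species lookup consumed by the survey
#' metrics: allometric length-weight parameters `a` (g cm^-b) and `b`,
#' herbivore functional group (grazer / scraper / browser / other), a
#' schooling flag, and a typical total length. The parameter values are
#' synthetic stand-ins of realistic magnitude, not measured coefficients.
#'
#' @return A data frame, one row per species.
#' @export
reef_species_table <- function() {
  data.frame(
    species_code = c("SCPS", "CHSP", "ACTR", "ACNF", "ZEFL",
                     "KYSA", "NALI", "CAME", "CEAR", "MUFL"),
    a = c(0.0136, 0.0158, 0.0213, 0.0244, 0.0280,
          0.0161, 0.0257, 0.0171, 0.0118, 0.0110),
    b = c(3.05, 3.01, 2.98, 2.94, 2.89, 3.02, 2.95, 3.00, 3.10, 3.05),
    functional_group = c("scraper", "scraper", "grazer", "grazer", "grazer",
                         "browser", "browser", "other", "other", "other"),
    herbivore = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    schooling = c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE),
    tl_typical = c(22, 18, 12, 10, 14, 30, 25, 35, 28, 20),
    stringsAsFactors = FALSE
  )
}

#' Synthetic inter-method calibration table
#'
#' Example species-by-method count calibration multipliers of the kind used to
#' reconcile survey methods across monitoring programs. Values are synthetic.
#'
#' @param species Optional species table (defaults to [reef_species_table()]).
#' @param methods Survey method labels.
#' @param seed RNG seed.
#' @return A data frame with `species_code`, `method`, `factor`.
#' @export
reef_calibration_table <- function(species = reef_species_table(),
                                   methods = c("belt", "spc"), seed = 1L) {
  set.seed(seed)
  out <- expand.grid(species_code = species$species_code, method = methods,
                     stringsAsFactors = FALSE)
  out$factor <- round(stats::runif(nrow(out), 0.8, 1.3), 3)
  out
}

#' Simulate a zero-inflated management-stratum dataset
#'
#' Generates presence/biomass records per management level from the hurdle
#' parameters in `truth`: presence is Bernoulli(`hurdle_p[level]`) and biomass
#' when present is gamma with mean `hurdle_mu[level]` and shape
#' `hurdle_kappa`; absent records have biomass exactly 0.
#'
#' @param levels Character vector of management levels; each must appear in
#'   `truth$hurdle_p` and `truth$hurdle_mu`.
#' @param truth A `reef_truth`.
#' @param n_per_level Observations per level.
#' @param seed Integer RNG seed.
#' @return A data frame with `management`, `present`, `biomass`.
#' @export
simulate_hurdle_case <- function(levels, truth, n_per_level, seed = 1L) {
  stopifnot(inherits(truth, "reef_truth"))
  n_per_level <- check_count(n_per_level, "n_per_level")
  unknown <- setdiff(levels, names(truth$hurdle_p))
  if (length(unknown))
    stopf("invalid argument: unknown management level(s): %s",
          paste(unknown, collapse = ", "))
  set.seed(seed)
  out <- lapply(levels, function(lv) {
    pres <- stats::rbinom(n_per_level, 1L, truth$hurdle_p[[lv]])
    mu <- truth$hurdle_mu[[lv]]
    k <- truth$hurdle_kappa
    bio <- ifelse(pres == 1L, stats::rgamma(n_per_level, shape = k, rate = k / mu), 0)
    data.frame(management = lv, present = pres, biomass = bio,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$management <- factor(out$management, levels = levels)
  rownames(out) <- NULL
  out
}
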