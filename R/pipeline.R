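# Configuration-driven orchestration: simulate -> prep -> fits -> threshold ->
# poststrat -> hurdle -> report, with per-stage artifacts, a hash manifest,
# and partial re-runs that reuse cached upstream artifacts from the output
# directory. The exported functions are the command surface: users drive the
# pipeline from R (or one-line Rscript calls) with a config list or YAML file.

stage_order <- c("simulate", "prep", "fit_herbivore", "fit_benthic",
                 "threshold", "poststrat", "hurdle", "report")

stage_deps <- list(
  simulate = character(0),
  prep = "simulate",
  fit_herbivore = "prep",
  fit_benthic = "prep",
  threshold = c("fit_herbivore", "fit_benthic"),
  poststrat = c("fit_herbivore", "threshold"),
  hurdle = "simulate",
  report = character(0)
)

#' Default pipeline configuration
#'
#' Returns the full configuration list with documented defaults; any entry can
#' be overridden by the `config` argument of [run_pipeline()] (or a YAML file
#' with the same structure). Key thresholds: Spearman screen `rho = 0.7`,
#' threshold probability `p_star = 0.99`, minimum replicates per moku
#' `min_n = 5`, benthic log-ratio floor `delta = 0.1`.
#'
#' @param outdir Output directory for artifacts.
#' @param seed Master seed; stage seeds are derived from it.
#' @return A named list.
#' @export
pipeline_config <- function(outdir = "reefherb_out", seed = 1L) {
  list(
    outdir = outdir,
    seed = as.integer(seed),
    stages = stage_order,
    n_pixels = 400L, n_moku = 4L, correlation_level = 0.3,
    n_replicates = 1200L, n_years = 3L, n_datasets = 2L,
    truth = list(
      beta = c(fishing_noncomm_boat_spear = -0.35, fishing_noncomm_boat_net = -0.25,
               pollution_urban_runoff = -0.15, ocean_wave_anom_max = 0.2,
               habitat_rugosity = 0.2, habitat_depth = -0.15)
    ),
    rho = 0.7, min_n = 5L, delta = 0.1, p_star = 0.99,
    mcmc = "ci",
    max_draws = 500L,
    hurdle = list(levels = c("open", "protected"), n_per_level = 400L, B = 1000L),
    inputs = list()
  )
}

md5_of <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(deparse(x), collapse = "\n"), f)
  unname(tools::md5sum(f))
}

stage_hash <- function(config, stage) {
  keys <- switch(stage,
    simulate = c("seed", "n_pixels", "n_moku", "correlation_level",
                 "n_replicates", "n_years", "n_datasets", "truth", "hurdle"),
    prep = c("seed", "rho", "min_n", "delta"),
    fit_herbivore = c("seed", "mcmc"),
    fit_benthic = c("seed", "mcmc"),
    threshold = c("seed", "p_star", "max_draws"),
    poststrat = c("seed", "max_draws"),
    hurdle = c("seed", "hurdle"),
    report = character(0)
  )
  md5_of(list(stage = stage, config = config[keys]))
}

#' Serialize / load a posterior fit as CSV + JSON metadata
#'
#' The draws file is a plain CSV with one column per parameter plus a `chain`
#' column; the side-car JSON carries the family, hierarchy levels,
#' coefficient names, column groups and design metadata, so a fit can be
#' reloaded for prediction in a later partial pipeline run.
#'
#' @param fit A `reef_fit`.
#' @param path Path of the draws CSV (metadata goes to `<path>.meta.json`).
#' @return `read_fit()` returns a prediction-capable `reef_fit` (without the
#'   training data); `write_fit()` the paths, invisibly.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "reef_fit"))
  utils::write.csv(data.frame(chain = fit$chain, fit$draws, check.names = FALSE),
                   path, row.names = FALSE)
  meta <- list(family = fit$family, beta_cols = fit$beta_cols,
               levels = fit$levels, groups = as.list(fit$groups),
               rhat = as.list(fit$rhat),
               design_meta = list(
                 spec = fit$design_meta$spec,
                 drivers = fit$design_meta$drivers,
                 fg_centers = as.list(fit$design_meta$fg_centers %||% list()),
                 habitat_levels = fit$design_meta$habitat_levels,
                 params = as.list(fit$design_meta$params)))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(c(path, paste0(path, ".meta.json")))
}

#' @rdname write_fit
#' @export
read_fit <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  draws <- as.matrix(tab[, setdiff(names(tab), "chain"), drop = FALSE])
  params <- as.data.frame(meta$design_meta$params)
  class(params) <- c("standardization_params", "data.frame")
  fg_centers <- unlist(meta$design_meta$fg_centers)
  structure(list(
    draws = draws, chain = tab$chain, family = meta$family,
    beta_cols = meta$beta_cols, levels = meta$levels,
    groups = unlist(meta$groups), rhat = unlist(meta$rhat),
    design_meta = list(spec = meta$design_meta$spec,
                       drivers = meta$design_meta$drivers,
                       fg_centers = if (length(fg_centers)) fg_centers else NULL,
                       habitat_levels = meta$design_meta$habitat_levels,
                       params = params),
    converged = all(unlist(meta$rhat) < 1.1, na.rm = TRUE)
  ), class = "reef_fit")
}

read_grid_csv <- function(path) {
  g <- utils::read.csv(path, stringsAsFactors = FALSE)
  attr(g, "driver_info") <- reef_driver_info()
  class(g) <- c("reef_grid", "data.frame")
  g
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order, writing per-stage
#' artifacts (CSV / JSON / YAML) and a `manifest.json` with a configuration
#' hash, seed and MD5 checksum per artifact. Deterministic stages reproduce
#' identical checksums for identical configuration and seed. When a stage is
#' not requested but its artifacts from a previous run exist in `outdir`,
#' they are reloaded (partial re-run); a missing dependency with no cached
#' artifacts is a configuration error raised before any stage runs.
#'
#' @param config A configuration list overriding [pipeline_config()] entries,
#'   or the path of a YAML file with such a list.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config error: file '%s' not found", config)
    config <- yaml::read_yaml(config)
    if (!is.null(config$truth$beta)) config$truth$beta <- unlist(config$truth$beta)
  }
  cfg <- utils::modifyList(pipeline_config(), config)
  stages <- intersect(stage_order, cfg$stages)
  if (!length(stages)) stopf("config error: no valid stages requested")
  if (length(cfg$inputs)) {
    missing <- unlist(cfg$inputs)[!file.exists(unlist(cfg$inputs))]
    if (length(missing))
      stopf("config error: input file(s) not found: %s", paste(missing, collapse = ", "))
  }
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)

  # pre-run dependency validation: every dependency must be requested or cached
  cached <- function(stage) {
    fs <- stage_files(stage, cfg$outdir)
    length(fs) > 0 && all(file.exists(fs))
  }
  for (s in stages) {
    need <- setdiff(stage_deps[[s]], stages)
    bad <- need[!vapply(need, cached, logical(1))]
    if (length(bad))
      stopf("config error: stage '%s' needs '%s' (not requested and no cached artifacts in %s)",
            s, paste(bad, collapse = ", "), cfg$outdir)
  }

  manifest <- list(config_seed = cfg$seed, stages = list())
  state <- list(cfg = cfg)
  for (s in stages) {
    state <- run_stage(s, state)
    files <- stage_files(s, cfg$outdir)
    files <- files[file.exists(files)]
    manifest$stages[[s]] <- list(
      hash = stage_hash(cfg, s), seed = cfg$seed,
      files = as.list(stats::setNames(unname(tools::md5sum(files)), basename(files)))
    )
  }
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

stage_files <- function(stage, outdir) {
  f <- switch(stage,
    simulate = c("grid.csv", "replicates.csv", "fish.csv", "hurdle_data.csv",
                 "truth.yml"),
    prep = c("replicates_prepped.csv", "standardization_params.csv",
             "retained_drivers.json"),
    fit_herbivore = c("fit_total.csv", "fit_total.csv.meta.json",
                      "fit_grazer.csv", "fit_grazer.csv.meta.json",
                      "fit_scraper.csv", "fit_scraper.csv.meta.json",
                      "fit_browser.csv", "fit_browser.csv.meta.json"),
    fit_benthic = c("fit_benthic.csv", "fit_benthic.csv.meta.json"),
    threshold = c("threshold.json", "pixel_counterfactual.csv"),
    poststrat = "area_summaries.csv",
    hurdle = "hurdle_results.json",
    report = "report.txt"
  )
  file.path(outdir, f)
}

need_artifact <- function(state, stage) {
  # load a cached upstream stage's artifacts when it was not run this session
  cfg <- state$cfg
  if (stage == "simulate" && is.null(state$grid)) {
    state$grid <- read_grid_csv(file.path(cfg$outdir, "grid.csv"))
    state$replicates <- utils::read.csv(file.path(cfg$outdir, "replicates.csv"))
    state$hurdle_data <- utils::read.csv(file.path(cfg$outdir, "hurdle_data.csv"))
    state$truth <- read_truth(file.path(cfg$outdir, "truth.yml"))
  }
  if (stage == "prep" && is.null(state$prepped)) {
    state$prepped <- utils::read.csv(file.path(cfg$outdir, "replicates_prepped.csv"))
    p <- utils::read.csv(file.path(cfg$outdir, "standardization_params.csv"))
    class(p) <- c("standardization_params", "data.frame")
    state$params <- p
    state$retained <- unlist(jsonlite::read_json(
      file.path(cfg$outdir, "retained_drivers.json"), simplifyVector = TRUE))
  }
  if (stage == "fit_herbivore" && is.null(state$fits)) {
    state$fits <- lapply(c(total = "fit_total.csv", grazer = "fit_grazer.csv",
                           scraper = "fit_scraper.csv", browser = "fit_browser.csv"),
                         function(f) read_fit(file.path(cfg$outdir, f)))
  }
  if (stage == "fit_benthic" && is.null(state$benthic_fit))
    state$benthic_fit <- read_fit(file.path(cfg$outdir, "fit_benthic.csv"))
  if (stage == "threshold" && is.null(state$threshold))
    state$threshold <- jsonlite::read_json(file.path(cfg$outdir, "threshold.json"),
                                           simplifyVector = TRUE)
  state
}

run_stage <- function(stage, state) {
  cfg <- state$cfg
  out <- cfg$outdir
  for (dep in stage_deps[[stage]]) state <- need_artifact(state, dep)

  if (stage == "simulate") {
    state$truth <- make_truth(cfg$truth)
    state$grid <- make_driver_grid(cfg$n_pixels, cfg$n_moku,
                                   cfg$correlation_level, seed = cfg$seed)
    sim <- simulate_surveys(state$grid, state$truth, cfg$n_replicates,
                            cfg$n_years, cfg$n_datasets, seed = cfg$seed + 1L)
    state$replicates <- sim$replicates
    state$fish <- sim$fish
    state$hurdle_data <- simulate_hurdle_case(cfg$hurdle$levels, state$truth,
                                              cfg$hurdle$n_per_level,
                                              seed = cfg$seed + 2L)
    utils::write.csv(state$grid, file.path(out, "grid.csv"), row.names = FALSE)
    utils::write.csv(sim$replicates, file.path(out, "replicates.csv"), row.names = FALSE)
    utils::write.csv(sim$fish, file.path(out, "fish.csv"), row.names = FALSE)
    utils::write.csv(state$hurdle_data, file.path(out, "hurdle_data.csv"),
                     row.names = FALSE)
    write_truth(state$truth, file.path(out, "truth.yml"))

  } else if (stage == "prep") {
    info <- reef_driver_info()
    reps <- filter_domain(state$replicates)
    reps <- drop_sparse_moku(reps, cfg$min_n)
    std <- standardize_drivers(reps, info$driver)
    scr <- correlation_screen(reps[, info$driver], threshold = cfg$rho)
    state$prepped <- reps
    state$params <- std$params
    state$retained <- scr$retained
    utils::write.csv(reps, file.path(out, "replicates_prepped.csv"), row.names = FALSE)
    utils::write.csv(std$params, file.path(out, "standardization_params.csv"),
                     row.names = FALSE)
    jsonlite::write_json(scr$retained, file.path(out, "retained_drivers.json"),
                         digits = NA)

  } else if (stage == "fit_herbivore") {
    metrics <- c(total = "biomass_total", grazer = "biomass_grazer",
                 scraper = "biomass_scraper", browser = "biomass_browser")
    params <- state$params[state$params$driver %in% state$retained, ]
    state$fits <- lapply(metrics, function(resp) {
      spec <- hier_spec(
        response = resp,
        design_fun = function(d) build_design(d, state$retained, params,
                                              spec = "herbivore"),
        family = "gamma-log",
        mcmc = mcmc_schedule(cfg$mcmc), seed = cfg$seed + 10L)
      fit_gamma_glm(spec, state$prepped)
    })
    for (m in names(metrics))
      write_fit(state$fits[[m]], file.path(out, sprintf("fit_%s.csv", m)))

  } else if (stage == "fit_benthic") {
    info <- reef_driver_info()
    benthic_drivers <- intersect(state$retained, c(
      info$driver[info$group %in% c("oceanography", "pollution")],
      "habitat_depth", "habitat_rugosity"))
    params <- state$params[state$params$driver %in% benthic_drivers, ]
    spec <- hier_spec(
      response = "benthic_logratio",
      design_fun = function(d) build_design(d, benthic_drivers, params,
                                            spec = "benthic"),
      family = "normal",
      mcmc = mcmc_schedule(cfg$mcmc), seed = cfg$seed + 11L)
    state$benthic_fit <- fit_normal_lm(spec, state$prepped)
    write_fit(state$benthic_fit, file.path(out, "fit_benthic.csv"))

  } else if (stage == "threshold") {
    grid_hard <- mask_softbottom(state$grid)
    cf <- predict_counterfactual(state$fits$total, grid_hard,
                                 max_draws = cfg$max_draws,
                                 moku_fallback = "population")
    state$cf <- cf
    fg_scenario <- function(which) {
      out <- lapply(c("grazer", "scraper", "browser"), function(g) {
        cfg_g <- predict_counterfactual(state$fits[[g]], grid_hard,
                                        max_draws = cfg$max_draws,
                                        moku_fallback = "population")
        colMeans(cfg_g[[which]])
      })
      stats::setNames(as.data.frame(out), c("grazer", "scraper", "browser"))
    }
    bcf <- benthic_counterfactual(state$benthic_fit, grid_hard,
                                  fg_scenario("expected"), fg_scenario("potential"),
                                  max_draws = cfg$max_draws,
                                  moku_fallback = "population")
    cls <- classify_pixel(bcf$expected, bcf$potential)
    thr <- fit_threshold_logistic(cls, cf$median_percent, p_star = cfg$p_star)
    cov <- threshold_coverage(cf$median_percent, thr, moku = grid_hard$moku_id)
    state$threshold <- list(
      x_star = thr$x_star, p_star = thr$p_star,
      intercept = thr$intercept, slope = thr$slope,
      separation = thr$separation, unreliable = thr$unreliable,
      fraction_below = cov$overall, by_moku = cov$by_moku,
      n_pixels = length(cls), n_affected = sum(cls == "affected"))
    jsonlite::write_json(state$threshold, file.path(out, "threshold.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(data.frame(
      pixel_id = cf$pixel_id, moku_id = cf$moku_id,
      median_percent_potential = cf$median_percent,
      classification = as.character(cls),
      below_threshold = cf$median_percent < thr$x_star),
      file.path(out, "pixel_counterfactual.csv"), row.names = FALSE)

  } else if (stage == "poststrat") {
    if (is.null(state$cf)) {
      grid_hard <- mask_softbottom(state$grid)
      state$cf <- predict_counterfactual(state$fits$total, grid_hard,
                                         max_draws = cfg$max_draws,
                                         moku_fallback = "population")
    }
    sums <- poststratify_area(state$cf$expected, state$cf$moku_id)
    sums <- rank_areas(sums)
    state$area_summaries <- sums
    utils::write.csv(sums, file.path(out, "area_summaries.csv"), row.names = FALSE)

  } else if (stage == "hurdle") {
    hb <- combine_and_bootstrap(state$hurdle_data, B = cfg$hurdle$B,
                                seed = cfg$seed + 20L)
    state$hurdle_result <- hb
    jsonlite::write_json(list(
      model_mode = hb$fit$model_mode,
      point = hb$point, tests = hb$fit$tests,
      fold_change = hb$fold_change, n_degenerate = hb$n_degenerate),
      file.path(out, "hurdle_results.json"), auto_unbox = TRUE, digits = NA)

  } else if (stage == "report") {
    write_report(out)
  }
  state
}

#' Write a human-readable report from pipeline artifacts
#'
#' Recomputes every reported number from the serialized artifacts (draws
#' files, threshold JSON, area and hurdle outputs) — nothing is
#' report-only. Sections whose stage artifacts are absent are listed as
#' missing rather than failing.
#'
#' @param outdir The pipeline output directory.
#' @param file Report file name within `outdir`.
#' @return The report path, invisibly.
#' @export
write_report <- function(outdir, file = "report.txt") {
  lines <- c("reefherb pipeline report", strrep("=", 40), "")
  fit_section <- function(path, title) {
    if (!file.exists(file.path(outdir, path)))
      return(sprintf("[missing section: %s — stage not run]", title))
    fit <- read_fit(file.path(outdir, path))
    cs <- coef_summary(fit)
    c(title, strrep("-", nchar(title)),
      sprintf("%-32s %8s %8s %8s %8s %8s", "parameter", "median",
              "l50", "u50", "l95", "u95"),
      sprintf("%-32s %8.3f %8.3f %8.3f %8.3f %8.3f", cs$parameter, cs$median,
              cs$l50, cs$u50, cs$l95, cs$u95), "")
  }
  lines <- c(lines, fit_section("fit_total.csv", "Herbivore biomass model (total)"))
  lines <- c(lines, fit_section("fit_benthic.csv", "Benthic condition model"))

  tj <- file.path(outdir, "threshold.json")
  if (file.exists(tj)) {
    t <- jsonlite::read_json(tj, simplifyVector = TRUE)
    lines <- c(lines, "Fishing-depletion threshold", strrep("-", 27),
               sprintf("P(unaffected) = %.2f at %%potential biomass = %.1f%%",
                       t$p_star, t$x_star),
               sprintf("fraction of pixels below threshold: %.3f", t$fraction_below),
               "")
  } else lines <- c(lines, "[missing section: threshold — stage not run]", "")

  aj <- file.path(outdir, "area_summaries.csv")
  if (file.exists(aj)) {
    a <- utils::read.csv(aj)
    lines <- c(lines, "Post-stratified area summaries", strrep("-", 30),
               sprintf("%-10s %8s %8s %8s %6s %4s", "area", "mean", "l50",
                       "u50", "n_pix", "Q"),
               sprintf("%-10s %8.2f %8.2f %8.2f %6d %4d", a$area_id, a$mean,
                       a$l50, a$u50, a$n_pixels, a$quartile), "")
  } else lines <- c(lines, "[missing section: poststrat — stage not run]", "")

  hj <- file.path(outdir, "hurdle_results.json")
  if (file.exists(hj)) {
    h <- jsonlite::read_json(hj, simplifyVector = TRUE)
    p <- as.data.frame(h$point)
    lines <- c(lines, "Management hurdle analysis", strrep("-", 26),
               sprintf("mode: %s", h$model_mode),
               sprintf("%-12s %6s %10s %10s %10s %10s", "level", "p",
                       "cond_mean", "combined", "lower", "upper"),
               sprintf("%-12s %6.3f %10.2f %10.2f %10.2f %10.2f", p$level,
                       p$p, p$cond_mean, p$combined, p$lower, p$upper),
               sprintf("fold-change %s -> %s: %.2f [%.2f, %.2f]",
                       h$fold_change$levels[1], h$fold_change$levels[2],
                       h$fold_change$estimate, h$fold_change$lower,
                       h$fold_change$upper), "")
  } else lines <- c(lines, "[missing section: hurdle — stage not run]", "")

  writeLines(lines, file.path(outdir, file))
  invisible(file.path(outdir, file))
}
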