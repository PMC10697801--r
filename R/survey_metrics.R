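# Survey metrics: from raw multi-institution fish/benthic records to analysis
# replicates — calibration, allometric biomass, schooling truncation, domain
# filters, replicate aggregation, functional groups, and the benthic log-ratio.

#' Assemble an allometric / calibration lookup
#'
#' Bundles the per-species allometric parameters (`a`, `b`, functional group,
#' herbivore flag) with an optional species-by-method calibration table into
#' the single lookup object consumed by the survey-metric operations.
#'
#' @param species Data frame with `species_code`, `a`, `b`, `functional_group`,
#'   `herbivore`.
#' @param calibration Optional data frame with `species_code`, `method`,
#'   `factor` (count multipliers, must be non-negative).
#' @return An object of class `allometric_table`.
#' @export
allometric_table <- function(species, calibration = NULL) {
  check_columns(species, c("species_code", "a", "b", "functional_group", "herbivore"),
                "species table")
  if (any(species$a <= 0) || any(species$b <= 0))
    stopf("invalid table: allometric a and b must be > 0")
  herb <- species$herbivore
  bad <- herb & !species$functional_group %in% c("grazer", "scraper", "browser")
  if (any(bad))
    stopf("invalid table: herbivore species without functional group: %s",
          paste(species$species_code[bad], collapse = ", "))
  if (!is.null(calibration)) {
    check_columns(calibration, c("species_code", "method", "factor"), "calibration table")
    if (any(calibration$factor < 0))
      stopf("invalid table: negative calibration factor")
  }
  structure(list(species = species, calibration = calibration),
            class = "allometric_table")
}

#' Apply species-and-method count calibration
#'
#' Multiplies observation counts by the species-by-method calibration factor,
#' reconciling survey methods across monitoring programs. Species/method pairs
#' absent from the calibration table keep their counts (factor 1) and are
#' reported in a single warning.
#'
#' @param observations Data frame with `species_code`, `count`, `method`.
#' @param table An [allometric_table()] carrying a calibration table.
#' @return The observations with calibrated `count`.
#' @export
calibrate_counts <- function(observations, table) {
  stopifnot(inherits(table, "allometric_table"))
  check_columns(observations, c("species_code", "count", "method"), "observations")
  cal <- table$calibration
  if (is.null(cal)) stopf("invalid table: no calibration table supplied")
  key <- paste(observations$species_code, observations$method, sep = "\r")
  fac <- cal$factor[match(key, paste(cal$species_code, cal$method, sep = "\r"))]
  miss <- is.na(fac)
  if (any(miss)) {
    pairs <- unique(paste0(observations$species_code[miss], "/",
                           observations$method[miss]))
    warnf("no calibration factor for %d observation(s) (%s); factor 1 used",
          sum(miss), paste(pairs, collapse = ", "))
    fac[miss] <- 1
  }
  observations$count <- observations$count * fac
  observations
}

#' Allometric biomass density
#'
#' Computes per-observation biomass density `count * a * TL^b / survey_area`
#' in g m^-2 from the length-weight power law `W = a * TL^b` (W in grams, TL
#' total length in cm). Unknown species are an error: silently dropping them
#' would bias biomass.
#'
#' @param observations Data frame with `species_code`, `count`,
#'   `total_length_cm`.
#' @param table An [allometric_table()].
#' @param survey_area Survey area in m^2 (> 0).
#' @return Numeric vector of biomass densities (g m^-2), one per observation.
#' @export
compute_biomass <- function(observations, table, survey_area) {
  stopifnot(inherits(table, "allometric_table"))
  check_columns(observations, c("species_code", "count", "total_length_cm"),
                "observations")
  if (!is.numeric(survey_area) || length(survey_area) != 1L || survey_area <= 0)
    stopf("invalid argument: survey_area must be a single value > 0")
  sp <- table$species
  i <- match(observations$species_code, sp$species_code)
  if (anyNA(i))
    stopf("missing parameter: no allometric parameters for species: %s",
          paste(unique(observations$species_code[is.na(i)]), collapse = ", "))
  observations$count * sp$a[i] * observations$total_length_cm^sp$b[i] / survey_area
}

#' Truncate extreme schooling counts
#'
#' Two-stage adjustment for spuriously large counts of schooling species:
#' observations whose count exceeds the upper 99.9% quantile of all individual
#' counts are flagged; for the flagged species that are herbivores (or all
#' flagged species when no species table is given), every count above the 99%
#' quantile across all observations is truncated to that 99% quantile. Both
#' quantiles use the sort-based (type 7) rule. Counts are never increased.
#'
#' @param observations Data frame with `species_code`, `count` (non-empty).
#' @param species_table Optional species table with `species_code`,
#'   `herbivore`; restricts truncation to flagged herbivore species.
#' @param flag_prob,trunc_prob Flagging and truncation quantile levels.
#' @return A list with `observations` (adjusted) and `report` (a data frame of
#'   modified records: row, species, original and truncated count, plus the
#'   two quantiles as attributes).
#' @export
truncate_schooling <- function(observations, species_table = NULL,
                               flag_prob = 0.999, trunc_prob = 0.99) {
  check_columns(observations, c("species_code", "count"), "observations")
  if (nrow(observations) == 0L) stopf("invalid argument: empty observation table")
  counts <- observations$count
  q_flag <- q7(counts, flag_prob)
  q_trunc <- q7(counts, trunc_prob)
  flagged_obs <- counts > q_flag
  flagged_sp <- unique(observations$species_code[flagged_obs])
  if (!is.null(species_table)) {
    check_columns(species_table, c("species_code", "herbivore"), "species table")
    herb <- species_table$species_code[species_table$herbivore]
    flagged_sp <- intersect(flagged_sp, herb)
  }
  target <- observations$species_code %in% flagged_sp & counts > q_trunc
  report <- data.frame(
    row = which(target),
    species_code = observations$species_code[target],
    original_count = counts[target],
    truncated_count = rep(q_trunc, sum(target))
  )
  observations$count[target] <- q_trunc
  attr(report, "flag_quantile") <- q_flag
  attr(report, "trunc_quantile") <- q_trunc
  attr(report, "flagged_species") <- flagged_sp
  list(observations = observations, report = report)
}

#' Restrict transects to the analysis domain
#'
#' Keeps hard-bottom transects between `depth_range` metres collected within
#' `years` — the reef habitat and pre-bleaching window the models are fit to.
#'
#' @param transects Data frame with `hardbottom` (logical), `depth_m`, `year`.
#' @param depth_range Inclusive depth window in metres.
#' @param years Inclusive year window.
#' @return The filtered transect table.
#' @export
filter_domain <- function(transects, depth_range = c(0, 30),
                          years = c(2004L, 2014L)) {
  check_columns(transects, c("hardbottom", "depth_m", "year"), "transects")
  keep <- transects$hardbottom &
    transects$depth_m >= depth_range[1] & transects$depth_m <= depth_range[2] &
    transects$year >= years[1] & transects$year <= years[2]
  keep[is.na(keep)] <- FALSE
  transects[keep, , drop = FALSE]
}

#' Aggregate transects into replicates
#'
#' A replicate is the analysis unit: all transects sharing data source,
#' latitude, longitude, depth and year (coordinates compared after rounding to
#' `coord_digits` decimals, since sources record differing precision). Metric
#' values are unweighted means over member transects; non-numeric metadata is
#' taken from the first member.
#'
#' @param transects Data frame with the key columns `source_dataset`,
#'   `latitude`, `longitude`, `depth_m`, `year` plus metric columns.
#' @param metric_cols Columns to average; defaults to all numeric non-key
#'   columns.
#' @param coord_digits Decimal places for coordinate matching.
#' @return One row per replicate key.
#' @export
aggregate_replicates <- function(transects, metric_cols = NULL, coord_digits = 5L) {
  key_cols <- c("source_dataset", "latitude", "longitude", "depth_m", "year")
  check_columns(transects, key_cols, "transects")
  tr <- transects
  tr$latitude <- round(tr$latitude, coord_digits)
  tr$longitude <- round(tr$longitude, coord_digits)
  if (is.null(metric_cols)) {
    num <- vapply(tr, is.numeric, logical(1))
    metric_cols <- setdiff(names(tr)[num], key_cols)
  }
  key <- interaction(tr[key_cols], drop = TRUE, lex.order = TRUE)
  first <- !duplicated(key)
  meta_cols <- setdiff(names(tr), metric_cols)
  out <- tr[first, meta_cols, drop = FALSE]
  ord <- order(key[first])
  out <- out[ord, , drop = FALSE]
  for (m in metric_cols)
    out[[m]] <- as.vector(tapply(tr[[m]], key, mean))
  out$n_transects <- as.vector(table(key))
  rownames(out) <- NULL
  out
}

#' Thin a densely monitored site to a single year
#'
#' Intensively monitored sites can dominate a compiled dataset; this keeps
#' only `keep_year` for the named site and leaves all other replicates
#' untouched. Site membership is by a site label column, or by a radius
#' around a point when `center` is given.
#'
#' @param replicates Replicate table.
#' @param site_label Site name to thin.
#' @param keep_year Year to retain at the site.
#' @param site_col Column holding site labels (default `"site"`).
#' @param center Optional `c(longitude, latitude)` defining the site by a
#'   radius instead of a label.
#' @param radius_km Radius in km for the point rule (default 2.5).
#' @return The thinned replicate table.
#' @export
subsample_site <- function(replicates, site_label, keep_year,
                           site_col = "site", center = NULL, radius_km = 2.5) {
  if (is.null(center)) {
    if (!site_col %in% names(replicates))
      stopf("invalid argument: no column '%s' to resolve site membership", site_col)
    at_site <- replicates[[site_col]] == site_label
    at_site[is.na(at_site)] <- FALSE
    if (!any(at_site) && !site_label %in% replicates[[site_col]])
      return(replicates)
  } else {
    check_columns(replicates, c("longitude", "latitude"), "replicates")
    d <- haversine_km(replicates$longitude, replicates$latitude,
                      center[1], center[2])
    at_site <- d <= radius_km
  }
  if (!any(at_site)) return(replicates)
  if (!any(replicates$year[at_site] == keep_year))
    warnf("site '%s' has no replicates in %s; site removed entirely",
          site_label, keep_year)
  drop <- at_site & replicates$year != keep_year
  replicates[!drop, , drop = FALSE]
}

haversine_km <- function(lon1, lat1, lon2, lat2) {
  r <- 6371
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

#' Drop moku with too few replicates
#'
#' Removes moku represented by fewer than `min_n` replicates, so hierarchical
#' moku effects are estimated from adequately sampled areas.
#'
#' @param replicates Replicate table with `moku_id`.
#' @param min_n Minimum replicates per moku (default 5).
#' @return The filtered table; a warning if everything is dropped.
#' @export
drop_sparse_moku <- function(replicates, min_n = 5L) {
  check_columns(replicates, "moku_id", "replicates")
  n <- table(replicates$moku_id)
  keep_moku <- names(n)[n >= min_n]
  out <- replicates[replicates$moku_id %in% keep_moku, , drop = FALSE]
  if (nrow(out) == 0L && nrow(replicates) > 0L)
    warnf("all moku have fewer than %d replicates; empty table returned", min_n)
  out
}

#' Assign herbivore functional groups
#'
#' Maps species codes to grazer / scraper / browser for herbivores and
#' `"other"` for non-herbivores. Herbivore species absent from the lookup are
#' an error (a silent drop would bias functional-group biomass); unknown
#' non-listed species are also an error.
#'
#' @param species_codes Character vector.
#' @param table An [allometric_table()].
#' @return Character vector of group labels, same length as `species_codes`.
#' @export
assign_functional_groups <- function(species_codes, table) {
  stopifnot(inherits(table, "allometric_table"))
  sp <- table$species
  i <- match(species_codes, sp$species_code)
  if (anyNA(i))
    stopf("missing parameter: species not in functional-group table: %s",
          paste(unique(species_codes[is.na(i)]), collapse = ", "))
  ifelse(sp$herbivore[i], sp$functional_group[i], "other")
}

#' Benthic condition log-ratio
#'
#' The log-ratio of calcified cover (coral + crustose coralline algae) to
#' macroalgal cover, `log((coral + cca + delta) / (macroalgae + delta))`.
#' Positive values indicate calcifier-dominated benthos, negative values
#' macroalgae-dominated. The floor constant `delta` (% cover) keeps the
#' statistic defined when a side is zero and cancels when both sides are
#' equal.
#'
#' @param coral,cca,macroalgae Percent covers in `[0, 100]` (vectorized).
#' @param delta Floor constant in % cover (default 0.1).
#' @return Numeric vector of unitless log-ratios.
#' @export
benthic_condition <- function(coral, cca, macroalgae, delta = 0.1) {
  covers <- c(coral, cca, macroalgae)
  if (any(is.na(covers)) || any(covers < 0) || any(covers > 100))
    stopf("invalid argument: covers must lie in [0, 100]")
  log((coral + cca + delta) / (macroalgae + delta))
}
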