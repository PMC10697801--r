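# Driver preparation: standardization with reusable parameters, a Spearman
# correlation screen, and model design matrices (herbivore and benthic specs).

#' Standardize driver columns to zero mean, unit variance
#'
#' Standardizes each driver column with its sample mean and SD and returns the
#' parameters so the same transformation can be re-applied to a prediction
#' grid (moments are never re-estimated at prediction time).
#'
#' @param values Data frame or matrix of driver columns.
#' @param driver_cols Columns to standardize (default: all numeric columns).
#' @return A list with `values` (standardized table) and `params` (an object
#'   of class `standardization_params`: driver, mean, sd).
#' @export
standardize_drivers <- function(values, driver_cols = NULL) {
  values <- as.data.frame(values)
  if (is.null(driver_cols))
    driver_cols <- names(values)[vapply(values, is.numeric, logical(1))]
  mu <- vapply(values[driver_cols], mean, numeric(1))
  sd_ <- vapply(values[driver_cols], stats::sd, numeric(1))
  if (any(sd_ == 0 | is.na(sd_)))
    stopf("degenerate driver: constant column(s): %s",
          paste(driver_cols[sd_ == 0 | is.na(sd_)], collapse = ", "))
  params <- structure(
    data.frame(driver = driver_cols, mean = mu, sd = sd_, row.names = NULL),
    class = c("standardization_params", "data.frame"))
  list(values = apply_standardization(values, params), params = params)
}

#' Re-apply stored standardization parameters
#'
#' @param values Data frame containing the drivers named in `params`.
#' @param params A `standardization_params` object.
#' @return `values` with the listed driver columns standardized.
#' @export
apply_standardization <- function(values, params) {
  stopifnot(inherits(params, "standardization_params"))
  values <- as.data.frame(values)
  check_columns(values, params$driver, "driver table")
  for (i in seq_len(nrow(params))) {
    d <- params$driver[i]
    values[[d]] <- (values[[d]] - params$mean[i]) / params$sd[i]
  }
  values
}

#' Screen out rank-correlated drivers
#'
#' Repeatedly finds the driver pair with the largest absolute Spearman
#' correlation above `threshold` and drops one member: the one appearing later
#' in `keep_preferences`, or (when neither is listed) the one with the larger
#' mean absolute correlation to the remaining drivers. Absolute values are
#' used because collinearity is sign-blind.
#'
#' @param values Data frame of driver columns (>= 2).
#' @param threshold Absolute Spearman correlation limit (default 0.7).
#' @param keep_preferences Optional character vector; earlier entries win
#'   conflicts.
#' @return A list with `retained` (driver names), `values` (the retained
#'   columns) and `dropped` (data frame: dropped, kept_over, rho).
#' @export
correlation_screen <- function(values, threshold = 0.7, keep_preferences = NULL) {
  values <- as.data.frame(values)
  if (ncol(values) < 2L) stopf("invalid argument: need at least 2 drivers")
  rho <- stats::cor(values, method = "spearman")
  keep <- colnames(values)
  dropped <- data.frame(dropped = character(0), kept_over = character(0),
                        rho = numeric(0))
  pref_rank <- function(d) {
    i <- match(d, keep_preferences)
    ifelse(is.na(i), length(keep_preferences) + 1L, i)
  }
  repeat {
    r <- abs(rho[keep, keep, drop = FALSE])
    diag(r) <- 0
    if (all(r <= threshold)) break
    ij <- which(r == max(r), arr.ind = TRUE)[1L, ]
    a <- keep[ij[1]]; b <- keep[ij[2]]
    ra <- pref_rank(a); rb <- pref_rank(b)
    if (ra != rb) {
      drop <- if (ra < rb) b else a
    } else {
      # tie-break: drop the member more correlated with everything else
      others <- setdiff(keep, c(a, b))
      ma <- if (length(others)) mean(abs(rho[a, others])) else 0
      mb <- if (length(others)) mean(abs(rho[b, others])) else 0
      drop <- if (ma > mb) a else b
    }
    kept <- setdiff(c(a, b), drop)
    dropped <- rbind(dropped, data.frame(dropped = drop, kept_over = kept,
                                         rho = rho[a, b]))
    keep <- setdiff(keep, drop)
  }
  list(retained = keep, values = values[, keep, drop = FALSE], dropped = dropped)
}

#' Build a model design matrix
#'
#' Two model specs are supported. `"herbivore"`: retained drivers enter
#' standardized (using `params`, estimated on the training replicates) plus
#' habitat-class indicator columns with `"other"` hard bottom as the reference
#' level. `"benthic"`: the three functional-group biomasses are
#' `log(1 + x)`-transformed, centered, and expanded into 3 main + 3 pairwise +
#' 1 three-way interaction columns (products of the centered terms), followed
#' by the standardized non-fishing drivers (oceanography, pollution, depth,
#' rugosity — fishing acts on the benthos only through herbivores, and
#' habitat class is circular with benthic cover). An intercept column is
#' always first.
#'
#' @param data Replicate (or pixel) table.
#' @param drivers Character vector of driver columns to include.
#' @param params `standardization_params` for those drivers.
#' @param spec `"herbivore"` or `"benthic"`.
#' @param habitat_col Habitat class column (herbivore spec).
#' @param habitat_levels Indicator coding levels; first is the reference.
#' @param fg_cols Functional-group biomass columns (benthic spec).
#' @param fg_centers Optional centering constants for the transformed
#'   functional-group terms; estimated from `data` when `NULL` and stored in
#'   the result for reuse at prediction time.
#' @return An object of class `reef_design`: list with `X` (matrix), `groups`
#'   (column group labels), and `meta` (centers, params, spec).
#' @export
build_design <- function(data, drivers, params, spec = c("herbivore", "benthic"),
                         habitat_col = "habitat_class",
                         habitat_levels = c("other", "reef", "pavement", "boulder"),
                         fg_cols = c(grazer = "biomass_grazer",
                                     scraper = "biomass_scraper",
                                     browser = "biomass_browser"),
                         fg_centers = NULL) {
  spec <- match.arg(spec)
  data <- as.data.frame(data)
  check_columns(data, drivers, "design data")
  std <- apply_standardization(data, params)
  Xd <- as.matrix(std[, drivers, drop = FALSE])
  groups <- driver_groups(drivers)

  if (spec == "herbivore") {
    check_columns(data, habitat_col, "design data")
    hab <- factor(data[[habitat_col]], levels = habitat_levels)
    if (anyNA(hab))
      stopf("spec error: habitat class outside declared levels: %s",
            paste(setdiff(unique(data[[habitat_col]]), habitat_levels), collapse = ", "))
    H <- sapply(habitat_levels[-1L], function(l) as.numeric(hab == l))
    if (is.null(dim(H))) H <- matrix(H, nrow = nrow(data),
                                     dimnames = list(NULL, habitat_levels[-1L]))
    colnames(H) <- paste0("habitat_", colnames(H))
    X <- cbind(`(Intercept)` = 1, Xd, H)
    groups <- c("intercept", groups, rep("habitat", ncol(H)))
    centers <- NULL
  } else {
    check_columns(data, unname(fg_cols), "design data")
    lg <- log1p(as.matrix(data[, unname(fg_cols), drop = FALSE]))
    colnames(lg) <- names(fg_cols)
    if (is.null(fg_centers)) fg_centers <- colMeans(lg)
    lgc <- sweep(lg, 2L, fg_centers[colnames(lg)])
    herb <- cbind(
      lgc,
      `grazer:scraper` = lgc[, "grazer"] * lgc[, "scraper"],
      `grazer:browser` = lgc[, "grazer"] * lgc[, "browser"],
      `scraper:browser` = lgc[, "scraper"] * lgc[, "browser"],
      `grazer:scraper:browser` = lgc[, "grazer"] * lgc[, "scraper"] * lgc[, "browser"]
    )
    X <- cbind(`(Intercept)` = 1, herb, Xd)
    groups <- c("intercept", rep("herbivore", ncol(herb)), groups)
    centers <- fg_centers
  }
  if (anyNA(X)) stopf("spec error: design matrix contains missing values")
  structure(list(X = X, groups = stats::setNames(groups, colnames(X)),
                 meta = list(spec = spec, params = params, drivers = drivers,
                             fg_centers = centers, habitat_levels = habitat_levels)),
            class = "reef_design")
}

driver_groups <- function(drivers) {
  info <- reef_driver_info()
  g <- info$group[match(drivers, info$driver)]
  g[is.na(g)] <- "driver"
  g
}
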