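# Counterfactual prediction and threshold detection: expected vs potential
# (fishing at native zero) herbivore biomass per pixel, benthic-condition
# counterfactuals, affected/unaffected classification, and the logistic
# threshold on % potential biomass.

# draws x pixels matrix of the linear predictor for new pixels: year and
# dataset effects at 0 (their sum-to-zero mean, a "typical year/source" map),
# moku effect at the fitted level
predict_mu_grid <- function(fit, X, moku, draw_idx,
                            moku_fallback = c("error", "population")) {
  moku_fallback <- match.arg(moku_fallback)
  B <- fit$draws[draw_idx, fit$beta_cols, drop = FALSE]
  mu <- B %*% t(X)
  mi <- match(moku, fit$levels$moku)
  if (anyNA(mi)) {
    if (moku_fallback == "error")
      stopf("prediction-level error: moku not in fitted levels: %s (set moku_fallback = 'population' to use the population level)",
            paste(unique(moku[is.na(mi)]), collapse = ", "))
  }
  eps <- fit$draws[draw_idx, paste0("eps_moku[", fit$levels$moku, "]"), drop = FALSE]
  eps <- cbind(eps, 0)  # population level for unknown moku
  mi[is.na(mi)] <- ncol(eps)
  mu + eps[, mi, drop = FALSE]
}

thin_draws <- function(fit, max_draws) {
  n <- nrow(fit$draws)
  if (is.null(max_draws) || n <= max_draws) seq_len(n)
  else round(seq(1L, n, length.out = max_draws))
}

#' Per-pixel expected and potential biomass posteriors
#'
#' For every pixel, computes matched posterior draws of the expected biomass
#' (measured drivers) and the potential biomass (fishing drivers set to their
#' native zero before standardization, all other drivers unchanged), and the
#' per-draw percent potential `100 * expected / potential`. Matched draws
#' (same posterior draw index in numerator and denominator) implement the
#' ratio-of-posteriors definition. Pixels whose fishing drivers are already
#' natively zero have percent potential identically 100.
#'
#' @param fit A gamma-family `reef_fit` of herbivore biomass.
#' @param grid A pixel table carrying the model's native driver columns,
#'   `habitat_class` and `moku_id`.
#' @param fishing_drivers Driver columns to zero; default: the fitted drivers
#'   in the `"fishing"` group.
#' @param max_draws Thin the posterior to at most this many draws (memory).
#' @param moku_fallback `"error"` (default) or `"population"` for pixels in
#'   moku unseen during fitting.
#' @return An object of class `reef_counterfactual`: `pixel_id`, draw
#'   matrices `expected`, `potential`, `percent` (draws x pixels, g m^-2 and
#'   %), and `median_percent` per pixel.
#' @export
predict_counterfactual <- function(fit, grid, fishing_drivers = NULL,
                                   max_draws = 1000L,
                                   moku_fallback = c("error", "population")) {
  stopifnot(inherits(fit, "reef_fit"))
  if (fit$family != "gamma-log")
    stopf("invalid argument: counterfactual prediction needs the gamma biomass fit")
  meta <- fit$design_meta
  if (meta$spec != "herbivore")
    stopf("invalid argument: fit must use the herbivore design")
  if (is.null(fishing_drivers))
    fishing_drivers <- meta$drivers[driver_groups(meta$drivers) == "fishing"]
  check_columns(grid, c(meta$drivers, "habitat_class", "moku_id"), "grid")

  des_e <- build_design(grid, meta$drivers, meta$params, spec = "herbivore",
                        habitat_levels = meta$habitat_levels)
  grid0 <- grid
  for (d in fishing_drivers) grid0[[d]] <- 0
  des_p <- build_design(grid0, meta$drivers, meta$params, spec = "herbivore",
                        habitat_levels = meta$habitat_levels)

  idx <- thin_draws(fit, max_draws)
  mu_e <- predict_mu_grid(fit, des_e$X, grid$moku_id, idx, moku_fallback)
  mu_p <- predict_mu_grid(fit, des_p$X, grid$moku_id, idx, moku_fallback)
  expected <- exp(mu_e)
  potential <- exp(mu_p)
  percent <- 100 * exp(mu_e - mu_p)
  structure(list(
    pixel_id = grid$pixel_id %||% seq_len(nrow(grid)),
    moku_id = grid$moku_id,
    expected = expected, potential = potential, percent = percent,
    median_percent = apply(percent, 2L, stats::median),
    draw_idx = idx, fishing_drivers = fishing_drivers
  ), class = "reef_counterfactual")
}

#' Paired benthic-condition posteriors under expected vs potential herbivores
#'
#' Evaluates the benthic model's linear predictor (no observation noise: the
#' comparison is of condition, not single-survey outcomes) at each pixel
#' twice: once with the posterior-mean functional-group biomasses under the
#' expected scenario and once under the potential (fishing-minimized)
#' scenario, with all other drivers at measured values.
#'
#' @param fit A normal-family `reef_fit` with the benthic design.
#' @param grid Pixel table with the benthic model's native driver columns and
#'   `moku_id`.
#' @param fg_expected,fg_potential Matrices/data frames (pixels x 3, columns
#'   `grazer`, `scraper`, `browser`) of posterior-mean functional-group
#'   biomass (g m^-2) under each scenario.
#' @param max_draws Posterior thinning bound.
#' @param moku_fallback See [predict_counterfactual()].
#' @return A list of class `reef_benthic_cf` with draw matrices `expected`
#'   and `potential` (draws x pixels).
#' @export
benthic_counterfactual <- function(fit, grid, fg_expected, fg_potential,
                                   max_draws = 1000L,
                                   moku_fallback = c("error", "population")) {
  stopifnot(inherits(fit, "reef_fit"))
  meta <- fit$design_meta
  if (meta$spec != "benthic")
    stopf("invalid argument: fit must use the benthic design")
  if (is.null(fg_expected) || is.null(fg_potential))
    stopf("invalid argument: both scenario functional-group means are required")
  fg_expected <- as.data.frame(fg_expected)
  fg_potential <- as.data.frame(fg_potential)
  check_columns(fg_expected, c("grazer", "scraper", "browser"), "fg_expected")
  check_columns(fg_potential, c("grazer", "scraper", "browser"), "fg_potential")
  check_columns(grid, meta$drivers, "grid")

  scen_design <- function(fg) {
    d <- cbind(grid, biomass_grazer = fg$grazer, biomass_scraper = fg$scraper,
               biomass_browser = fg$browser)
    build_design(d, meta$drivers, meta$params, spec = "benthic",
                 fg_centers = meta$fg_centers)
  }
  idx <- thin_draws(fit, max_draws)
  mu_e <- predict_mu_grid(fit, scen_design(fg_expected)$X, grid$moku_id, idx,
                          moku_fallback)
  mu_p <- predict_mu_grid(fit, scen_design(fg_potential)$X, grid$moku_id, idx,
                          moku_fallback)
  structure(list(expected = mu_e, potential = mu_p, draw_idx = idx),
            class = "reef_benthic_cf")
}

#' Classify pixels as affected or unaffected by fishing
#'
#' A pixel is `affected` when the 25th percentile of its benthic-condition
#' posterior under potential biomass exceeds the 75th percentile under
#' expected biomass (the 50% intervals separate, with the potential interval
#' higher); otherwise `unaffected`. Quantiles use the sort-based (type 7)
#' rule.
#'
#' @param expected,potential Draw matrices (draws x pixels) or vectors for a
#'   single pixel.
#' @return Factor vector with levels `affected`, `unaffected`.
#' @export
classify_pixel <- function(expected, potential) {
  if (is.null(dim(expected))) expected <- matrix(expected, ncol = 1L)
  if (is.null(dim(potential))) potential <- matrix(potential, ncol = 1L)
  if (nrow(expected) == 0L || nrow(potential) == 0L)
    stopf("invalid argument: empty draw matrices")
  if (ncol(expected) != ncol(potential))
    stopf("invalid argument: scenario matrices must cover the same pixels")
  q75_e <- apply(expected, 2L, q7, 0.75)
  q25_p <- apply(potential, 2L, q7, 0.25)
  factor(ifelse(q25_p > q75_e, "affected", "unaffected"),
         levels = c("affected", "unaffected"))
}

#' Logistic threshold on % potential biomass
#'
#' Fits `unaffected (1) / affected (0) ~ median % potential biomass` by
#' maximum-likelihood logistic regression and solves, by exact logit
#' inversion, the % potential biomass `x*` at which the probability of being
#' unaffected reaches `p_star`. Under complete separation the fit is flagged
#' and the midpoint of the gap between classes is reported instead. A Wald
#' 95% slope interval containing 0 flags the threshold as unreliable.
#'
#' @param classification Factor from [classify_pixel()] (or logical
#'   `unaffected`).
#' @param percent_potential Median % potential biomass per pixel.
#' @param p_star Probability defining the threshold (default 0.99).
#' @return An object of class `threshold_result`: `intercept`, `slope`,
#'   `x_star`, `p_star`, `separation`, `unreliable`, the fitted `model` and
#'   the input classification table.
#' @export
fit_threshold_logistic <- function(classification, percent_potential,
                                   p_star = 0.99) {
  if (is.logical(classification)) {
    unaff <- classification
  } else {
    classification <- as.factor(classification)
    unaff <- classification == "unaffected"
  }
  if (length(unaff) != length(percent_potential))
    stopf("invalid argument: classification and percent_potential lengths differ")
  if (all(unaff) || all(!unaff))
    stopf("no-threshold error: both affected and unaffected pixels are required")

  separation <- max(percent_potential[!unaff]) < min(percent_potential[unaff])
  fit <- suppressWarnings(
    stats::glm(unaff ~ percent_potential, family = stats::binomial()))
  b <- stats::coef(fit)
  if (separation) {
    x_star <- (max(percent_potential[!unaff]) + min(percent_potential[unaff])) / 2
    unreliable <- FALSE
  } else {
    if (b[2] <= 0) {
      warnf("non-positive slope: unaffected probability does not increase with %% potential biomass")
    }
    x_star <- (stats::qlogis(p_star) - b[1]) / b[2]
    se <- sqrt(diag(stats::vcov(fit)))[2]
    slope_ci <- b[2] + c(-1, 1) * stats::qnorm(0.975) * se
    unreliable <- slope_ci[1] <= 0 && slope_ci[2] >= 0
    if (unreliable)
      warnf("threshold unreliable: 95%% slope interval contains 0")
  }
  structure(list(
    intercept = unname(b[1]), slope = unname(b[2]),
    x_star = unname(x_star), p_star = p_star,
    separation = separation, unreliable = unreliable,
    model = fit,
    classification = data.frame(percent_potential = percent_potential,
                                unaffected = unaff)
  ), class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("Logistic threshold: P(unaffected) = %.2f at %%potential = %.1f%%\n",
              x$p_star, x$x_star))
  cat(sprintf("  intercept %.3f, slope %.4f%s%s\n", x$intercept, x$slope,
              if (x$separation) " [complete separation: mid-gap threshold]" else "",
              if (x$unreliable) " [UNRELIABLE: slope CI contains 0]" else ""))
  invisible(x)
}

#' Fraction of pixels below the threshold
#'
#' @param percent_potential Median % potential biomass per pixel.
#' @param threshold A `threshold_result` or a numeric threshold in %.
#' @param moku Optional moku label per pixel for a per-area breakdown.
#' @param hardbottom Optional logical filter (soft-bottom pixels dropped).
#' @return A list with `overall` (fraction in `[0, 1]`) and `by_moku` (data
#'   frame with `moku_id`, `fraction_below`, `n_pixels`), or just the overall
#'   fraction when `moku` is `NULL`.
#' @export
threshold_coverage <- function(percent_potential, threshold, moku = NULL,
                               hardbottom = NULL) {
  x_star <- if (inherits(threshold, "threshold_result")) threshold$x_star
            else threshold
  keep <- is.finite(percent_potential)
  if (!is.null(hardbottom)) keep <- keep & hardbottom
  pp <- percent_potential[keep]
  overall <- mean(pp < x_star)
  if (is.null(moku)) return(list(overall = overall, by_moku = NULL))
  mk <- moku[keep]
  agg <- tapply(pp < x_star, mk, mean)
  list(overall = overall,
       by_moku = data.frame(moku_id = names(agg),
                            fraction_below = as.vector(agg),
                            n_pixels = as.vector(table(mk)),
                            row.names = NULL))
}
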