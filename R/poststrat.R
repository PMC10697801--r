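# Post-stratified prediction summaries: equal-weight pooling of per-pixel
# posterior draws within areas of interest (moku, reserves), and area ranking.

#' Mask soft-bottom pixels
#'
#' The survey domain is hard bottom, so area summaries exclude pixels
#' dominated by soft bottom.
#'
#' @param grid Pixel table with a logical `hardbottom_flag` column.
#' @return The hard-bottom subset; a warning if nothing remains.
#' @export
mask_softbottom <- function(grid) {
  check_columns(grid, "hardbottom_flag", "grid")
  out <- grid[grid$hardbottom_flag %in% TRUE, , drop = FALSE]
  if (nrow(out) == 0L && nrow(grid) > 0L)
    warnf("no hard-bottom pixels remain after masking")
  out
}

#' Post-stratified area summaries of pixel posteriors
#'
#' For each area, concatenates the full posterior draws of all member pixels
#' (each pixel one vote — the equal-weight convention that makes area
#' estimates reflect the distribution of habitat and drivers rather than
#' survey allocation) and summarizes the pooled draws: mean and the central
#' 50% interval (sort-based quantiles).
#'
#' @param pixel_draws Draws x pixels matrix of posterior predictions.
#' @param areas Area label per pixel (length `ncol(pixel_draws)`); `NA`
#'   pixels are ignored.
#' @return A data frame of class `area_summary`: `area_id`, `mean`, `l50`,
#'   `u50`, `n_pixels`. Areas with no pixels are skipped with a warning.
#' @export
poststratify_area <- function(pixel_draws, areas) {
  if (is.null(dim(pixel_draws)))
    pixel_draws <- matrix(pixel_draws, ncol = length(pixel_draws))
  if (ncol(pixel_draws) != length(areas))
    stopf("invalid argument: one area label per pixel column is required")
  f <- if (is.factor(areas)) areas else factor(areas)
  empty <- setdiff(levels(f), unique(as.character(f[!is.na(f)])))
  if (length(empty))
    warnf("area(s) with no pixels skipped: %s", paste(empty, collapse = ", "))
  ids <- intersect(levels(f), unique(as.character(f[!is.na(f)])))
  rows <- lapply(ids, function(a) {
    pooled <- as.vector(pixel_draws[, which(f == a), drop = FALSE])
    data.frame(area_id = a, mean = mean(pooled),
               l50 = q7(pooled, 0.25), u50 = q7(pooled, 0.75),
               n_pixels = sum(f == a, na.rm = TRUE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("area_summary", "data.frame")
  out
}

#' Rank areas into quartiles and against a reference posterior
#'
#' Labels each area by the quartile of its posterior mean (1 = lowest fourth,
#' 4 = highest fourth, by rank so group sizes are as equal as possible).
#' When a reference posterior summary is supplied (e.g. pooled no-take
#' reserves), an area is `lower_than_reference` when its 50% interval lies
#' entirely below the reference's 50% interval.
#'
#' @param summaries An `area_summary` data frame.
#' @param reference Optional list or one-row data frame with `l50`, `u50`.
#' @return `summaries` with `quartile` (integer, `NA` when fewer than 4
#'   areas) and, given a reference, `lower_than_reference`.
#' @export
rank_areas <- function(summaries, reference = NULL) {
  stopifnot(is.data.frame(summaries))
  check_columns(summaries, c("area_id", "mean", "l50", "u50"), "area summaries")
  n <- nrow(summaries)
  if (n >= 4L) {
    summaries$quartile <- ceiling(4 * rank(summaries$mean, ties.method = "first") / n)
  } else {
    warnf("quartiles unavailable with fewer than 4 areas")
    summaries$quartile <- NA_integer_
  }
  if (!is.null(reference)) {
    summaries$lower_than_reference <- summaries$u50 < reference$l50
  }
  summaries
}
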