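#' @keywords internal
"_PACKAGE"

# sort-based (type 7) quantile used everywhere a quartile/quantile rule is needed,
# so classification, truncation and pooled-interval code share one convention
q7 <- function(x, probs) stats::quantile(x, probs = probs, type = 7, names = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != floor(x) || x < min)
    stopf("invalid argument: `%s` must be a single integer >= %d", name, min)
  as.integer(x)
}

check_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stopf("schema error: %s is missing column(s): %s", what, paste(miss, collapse = ", "))
  invisible(df)
}

# expand L-1 free sum-to-zero effects to the full L-vector (last = -sum of others);
# a single-level hierarchy has no free parameters and an effect fixed at zero
expand_sum_to_zero <- function(z, n_levels) {
  if (n_levels == 1L) return(0)
  c(z, -sum(z))
}
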