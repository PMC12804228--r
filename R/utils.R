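#' Linear-interpolation percentile
#'
#' The single percentile convention used throughout the package: linear
#' interpolation between the closest order statistics (`stats::quantile`
#' type 7). Applied identically to static COF (95th percentile), dynamic
#' COF (median), AE RMS statistics and the in-band spectral percentile.
#'
#' @param x numeric vector (NAs dropped).
#' @param p percentile in \[0, 100\].
#' @return scalar percentile value.
#' @export
pctl <- function(x, p) {
  x <- x[!is.na(x)]
  if (!length(x)) stop("pctl(): no non-missing values", call. = FALSE)
  unname(stats::quantile(x, probs = p / 100, type = 7, names = FALSE))
}

# internal: scalar validation helpers ---------------------------------------

stopifnot_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    stop(sprintf("'%s' must be a single number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  invisible(x)
}

stopifnot_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be TRUE or FALSE", name), call. = FALSE)
  invisible(x)
}

# internal: box-plot five-number summary with 1.5 x IQR whiskers
boxplot_stats <- function(x) {
  x <- x[!is.na(x)]
  q1 <- pctl(x, 25); q2 <- pctl(x, 50); q3 <- pctl(x, 75)
  iqr <- q3 - q1
  lo_fence <- q1 - 1.5 * iqr
  hi_fence <- q3 + 1.5 * iqr
  inside <- x[x >= lo_fence & x <= hi_fence]
  list(n = length(x), median = q2, q1 = q1, q3 = q3,
       whisker_low  = if (length(inside)) min(inside) else q1,
       whisker_high = if (length(inside)) max(inside) else q3,
       n_outliers = sum(x < lo_fence | x > hi_fence),
       outliers = x[x < lo_fence | x > hi_fence])
}
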