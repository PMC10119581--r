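#' Analytic AUROC variance from the Mann-Whitney null distribution
#'
#' Uses the equal-group-size null variance of U, sigma^2_U = n^2 (2n+1) / 12,
#' so that var(AUROC) = var(U / n^2) = (2n + 1) / (12 n^2). `n` is the
#' per-group sample size in that equal-group form. For unequal groups the
#' general null variance is n m (n + m + 1) / 12; it is not used here because
#' the analytic pipeline is parameterised by a single effective sample size.
#'
#' @param n Positive integer sample size.
#' @return The variance (2n + 1) / (12 n^2).
#' @examples
#' var_auroc_mann_whitney(10)  # 21/1200 = 0.0175
#' @export
var_auroc_mann_whitney <- function(n) {
  check_n(n)
  (2 * n + 1) / (12 * n^2)
}

#' Large-sample AUROC variance approximation
#'
#' The limit of [var_auroc_mann_whitney()] as n grows: 1 / (6 n). The ratio
#' of the two equals 2n / (2n + 1), within 1\% for n >= 50.
#'
#' @inheritParams var_auroc_mann_whitney
#' @return The variance 1 / (6 n).
#' @export
var_auroc_large_n <- function(n) {
  check_n(n)
  1 / (6 * n)
}

#' Binomial-proportion variance of a classification metric
#'
#' Treats a metric p in \[0, 1\] (accuracy, F1, sensitivity, specificity,
#' PPV, NPV, and — as an approximation valid for values between about 0.7
#' and 0.9 — the AUROC) as a proportion of n subjects: var = p (1 - p) / n.
#'
#' @param p Metric value in \[0, 1\].
#' @param n Positive integer sample size (the test-set size, by default).
#' @return The variance p (1 - p) / n.
#' @examples
#' sqrt(var_proportion(0.789, 286))  # sd ~ 0.024
#' @export
var_proportion <- function(p, n) {
  check_n(n)
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("`p` must lie in [0, 1]", call. = FALSE)
  }
  p * (1 - p) / n
}

check_n <- function(n) {
  if (!is.numeric(n) || any(!is.finite(n)) || any(n < 1)) {
    stop("`n` must be a positive sample size (n >= 1)", call. = FALSE)
  }
  invisible(n)
}

#' Construct an analytically derived distribution (ADD)
#'
#' An ADD is a Gaussian for a model metric, specified by its point estimate
#' (the mean) and an analytic variance. The variance comes from one of three
#' formulas: `"proportion"` (p(1-p)/n, the default, applicable to all the
#' panel metrics), `"mann_whitney"` ((2n+1)/(12 n^2), AUROC only), or
#' `"large_n"` (1/(6n), AUROC only). Note the two AUROC-specific formulas are
#' null variances and do not depend on the point estimate.
#'
#' A degenerate estimate (p of exactly 0 or 1 under the proportion method)
#' yields variance 0 and is flagged via the `degenerate` field.
#'
#' @param point_estimate Metric value in \[0, 1\].
#' @param n Sample size entering the variance formula (conventionally the
#'   test-set size; see the vignette for why).
#' @param method One of `"proportion"`, `"mann_whitney"`, `"large_n"`.
#' @param clamp Optional length-2 numeric `c(min, max)`: empirical support
#'   bounds (e.g. the min/max of a companion resampling run) used for the
#'   minimum/maximum columns of summary tables.
#' @return An `add_spec` object: list with `point_estimate`, `n`, `variance`,
#'   `sd`, `method`, `support_min`, `support_max`, `degenerate`.
#' @examples
#' add_spec(0.868, 286)          # Gaussian mean 0.868, sd ~ 0.020
#' add_spec(0.868, 286, method = "mann_whitney")
#' @export
add_spec <- function(point_estimate, n,
                     method = c("proportion", "mann_whitney", "large_n"),
                     clamp = NULL) {
  method <- match.arg(method)
  check_n(n)
  if (!is.numeric(point_estimate) || length(point_estimate) != 1L ||
      !is.finite(point_estimate) || point_estimate < 0 || point_estimate > 1) {
    stop("`point_estimate` must be a single value in [0, 1]", call. = FALSE)
  }
  variance <- switch(method,
    proportion   = var_proportion(point_estimate, n),
    mann_whitney = var_auroc_mann_whitney(n),
    large_n      = var_auroc_large_n(n)
  )
  if (!is.null(clamp)) {
    if (length(clamp) != 2L || !all(is.finite(clamp)) || clamp[1] > clamp[2]) {
      stop("`clamp` must be c(min, max) with min <= max", call. = FALSE)
    }
  }
  structure(list(
    point_estimate = point_estimate,
    n = as.integer(n),
    variance = variance,
    sd = sqrt(variance),
    method = method,
    support_min = if (is.null(clamp)) NA_real_ else clamp[1],
    support_max = if (is.null(clamp)) NA_real_ else clamp[2],
    degenerate = variance == 0
  ), class = "add_spec")
}

#' @export
print.add_spec <- function(x, ...) {
  cat(sprintf("ADD: Normal(mean = %.4g, sd = %.4g)  [%s, n = %d]%s\n",
              x$point_estimate, x$sd, x$method, x$n,
              if (x$degenerate) "  (degenerate)" else ""))
  invisible(x)
}

#' Nine-statistic quantile summary of an ADD Gaussian
#'
#' Produces the row format used throughout the comparison tables: minimum,
#' 5th/25th/50th/75th/95th percentiles, maximum, mean, SD (plus range).
#' Percentiles are closed-form Gaussian quantiles mean + z_q * sd. The
#' minimum/maximum come from the `clamp` bounds of the spec when provided
#' (matching tables whose extremes are taken from a companion resampling
#' run); in pure-analytic mode they are the extreme Gaussian quantiles at
#' probability 1e-4 / 1 - 1e-4 — a documented convention, not a hard support.
#'
#' @param spec An `add_spec`.
#' @param round_digits Optional integer; if given, every statistic is rounded
#'   half-away-from-zero to that many decimals (tables use 3).
#' @return A `quantile_summary`: named numeric vector with elements
#'   `minimum, p5, p25, median, p75, p95, maximum, mean, sd, range`.
#' @examples
#' gaussian_quantile_summary(add_spec(0.789, 286), round_digits = 3)
#' @export
gaussian_quantile_summary <- function(spec, round_digits = NULL) {
  stopifnot(inherits(spec, "add_spec"))
  m <- spec$point_estimate
  s <- spec$sd
  q <- m + stats::qnorm(c(0.05, 0.25, 0.5, 0.75, 0.95)) * s
  lo <- if (is.na(spec$support_min)) m + stats::qnorm(1e-4) * s else spec$support_min
  hi <- if (is.na(spec$support_max)) m + stats::qnorm(1 - 1e-4) * s else spec$support_max
  # clamp bounds may be tighter than the nominal tail quantiles; keep ordering
  vals <- sort(c(lo, q, hi))
  quantile_summary(
    minimum = vals[1], p5 = vals[2], p25 = vals[3], median = vals[4],
    p75 = vals[5], p95 = vals[6], maximum = vals[7], mean = m, sd = s,
    round_digits = round_digits
  )
}

#' @rdname gaussian_quantile_summary
#' @param minimum,p5,p25,median,p75,p95,maximum,mean,sd The nine statistics.
#' @export
quantile_summary <- function(minimum, p5, p25, median, p75, p95, maximum,
                             mean, sd, round_digits = NULL) {
  x <- c(minimum = minimum, p5 = p5, p25 = p25, median = median, p75 = p75,
         p95 = p95, maximum = maximum, mean = mean, sd = sd)
  if (is.unsorted(x[1:7], na.rm = TRUE)) {
    stop("quantile summary must be monotone from minimum to maximum",
         call. = FALSE)
  }
  x <- c(x, range = unname(x["maximum"] - x["minimum"]))
  if (!is.null(round_digits)) x <- round_half_up(x, round_digits)
  structure(x, class = c("quantile_summary", "numeric"))
}

#' Summarise an empirical sample in the nine-statistic row format
#'
#' Quantiles use linear interpolation (`stats::quantile` type 7); mean and SD
#' are the usual sample moments (SD with the n-1 denominator). Missing values
#' are dropped with a warning carrying the count.
#'
#' @param values Numeric vector with at least 2 non-missing values.
#' @inheritParams gaussian_quantile_summary
#' @return A `quantile_summary`.
#' @export
empirical_summary <- function(values, round_digits = NULL) {
  n_missing <- sum(is.na(values))
  if (n_missing > 0) {
    warning(sprintf("dropped %d missing value(s)", n_missing), call. = FALSE)
    values <- values[!is.na(values)]
  }
  if (length(values) < 2L) {
    stop("need at least 2 non-missing values", call. = FALSE)
  }
  q <- stats::quantile(values, c(0, 0.05, 0.25, 0.5, 0.75, 0.95, 1),
                       names = FALSE, type = 7)
  quantile_summary(
    minimum = q[1], p5 = q[2], p25 = q[3], median = q[4], p75 = q[5],
    p95 = q[6], maximum = q[7], mean = mean(values), sd = stats::sd(values),
    round_digits = round_digits
  )
}

# round half away from zero (base round() is half-to-even)
round_half_up <- function(x, digits = 3) {
  pow <- 10^digits
  sign(x) * floor(abs(x) * pow + 0.5) / pow
}
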