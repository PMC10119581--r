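#' Anderson-Darling statistic for composite normality
#'
#' Tests whether a sample is compatible with a normal distribution when both
#' the mean and the SD are estimated from the sample itself (the relevant
#' case for resampling output, whose true moments are unknown). The sample is
#' standardized with its own mean and SD, sorted (stable sort; ties are not
#' jittered), and
#' \deqn{A^2 = -n - \frac{1}{n}\sum_{i=1}^n (2i-1)\,[\ln\Phi(z_{(i)}) +
#'   \ln(1-\Phi(z_{(n+1-i)}))].}
#' The small-sample corrected statistic is
#' \eqn{A^{*2} = A^2 (1 + 0.75/n + 2.25/n^2)}.
#'
#' @param values Numeric sample, n >= 8, non-constant.
#' @return An `ad_result`: list with `a_squared`, `a_squared_modified`,
#'   `p_value`, `n`, `estimated_mean`, `estimated_sd`.
#' @examples
#' ad_statistic(rnorm(200))
#' @export
ad_statistic <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 8) stop("Anderson-Darling test needs n >= 8", call. = FALSE)
  m <- mean(values)
  s <- stats::sd(values)
  if (s == 0) stop("constant sample: sd is zero", call. = FALSE)
  z <- sort((values - m) / s, method = "radix")
  # log forms keep the tail terms finite for |z| up to ~ 38
  log_phi <- stats::pnorm(z, log.p = TRUE)
  log_phi_c <- stats::pnorm(z, lower.tail = FALSE, log.p = TRUE)
  i <- seq_len(n)
  a2 <- -n - mean((2 * i - 1) * (log_phi + rev(log_phi_c)))
  a2_mod <- a2 * (1 + 0.75 / n + 2.25 / n^2)
  structure(list(
    a_squared = a2,
    a_squared_modified = a2_mod,
    p_value = ad_p_value(a2_mod),
    n = n,
    estimated_mean = m,
    estimated_sd = s
  ), class = "ad_result")
}

#' @export
print.ad_result <- function(x, ...) {
  cat(sprintf("Anderson-Darling composite normality: A*^2 = %.4g, p = %.4g (n = %d)\n",
              x$a_squared_modified, x$p_value, x$n))
  invisible(x)
}

#' p-value for the corrected Anderson-Darling statistic
#'
#' Piecewise exponential approximation for the composite-normality case (both
#' parameters estimated), using the D'Agostino-Stephens coefficients.
#' Monotone decreasing in the statistic; values capped to \[1e-7, 1\].
#'
#' @param a_squared_modified Corrected statistic `A*^2 >= 0`.
#' @return p-value in \[1e-7, 1\].
#' @export
ad_p_value <- function(a_squared_modified) {
  a <- a_squared_modified
  if (any(!is.finite(a)) || any(a < 0)) {
    stop("`a_squared_modified` must be non-negative", call. = FALSE)
  }
  p <- ifelse(a < 0.2,  1 - exp(-13.436 + 101.14 * a - 223.73 * a^2),
       ifelse(a < 0.34, 1 - exp(-8.318 + 42.796 * a - 59.938 * a^2),
       ifelse(a < 0.6,  exp(0.9177 - 4.279 * a - 1.38 * a^2),
                        exp(1.2937 - 5.709 * a + 0.0186 * a^2))))
  pmin(pmax(p, 1e-7), 1)
}

#' Normality sufficiency report for a replicate archive
#'
#' One Anderson-Darling test per archived metric and per gain covariate. A
#' distribution is flagged `normal_compatible` when p > alpha: then its mean
#' and SD are treated as sufficient statistics — the premise under which an
#' analytic Gaussian can stand in for the full resampled distribution.
#' Columns with missing or constant values are skipped; the skipped names and
#' reasons are attached as the `"skipped"` attribute.
#'
#' @param archive A `replicate_archive`.
#' @param alpha Flagging level (default 0.05).
#' @return Data frame with columns `name`, `type` (`"metric"`/`"gain"`), `n`,
#'   `a_squared_modified`, `p_value`, `normal_compatible`.
#' @export
sufficiency_report <- function(archive, alpha = 0.05) {
  stopifnot(inherits(archive, "replicate_archive"))
  if (nrow(archive$panels) == 0) stop("empty archive", call. = FALSE)

  blocks <- list(metric = archive$panels[metric_names()])
  if (!is.null(archive$gains)) blocks$gain <- archive$gains

  rows <- list()
  skipped <- character()
  for (type in names(blocks)) {
    block <- blocks[[type]]
    for (nm in names(block)) {
      x <- block[[nm]]
      if (any(is.na(x))) {
        skipped[nm] <- sprintf("%d undefined value(s)", sum(is.na(x)))
        next
      }
      if (length(x) < 8 || stats::sd(x) == 0) {
        skipped[nm] <- "constant or too short"
        next
      }
      ad <- ad_statistic(x)
      rows[[length(rows) + 1L]] <- data.frame(
        name = nm, type = type, n = ad$n,
        a_squared_modified = ad$a_squared_modified,
        p_value = ad$p_value,
        normal_compatible = ad$p_value > alpha
      )
    }
  }
  if (length(rows) == 0) stop("no testable columns in archive", call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Write the sufficiency report CSV
#'
#' Two blocks (model metrics, then gain covariates), columns `name` and
#' `p_value` at 2 decimals — the layout of the published normality table.
#'
#' @param report Output of [sufficiency_report()].
#' @param path CSV path.
#' @export
write_sufficiency_csv <- function(report, path) {
  out <- data.frame(
    Block = ifelse(report$type == "metric", "Model metrics", "Gain statistics"),
    Name = report$name,
    `Anderson-Darling p` = round_half_up(report$p_value, 2),
    check.names = FALSE
  )
  utils::write.csv(out[order(out$Block != "Model metrics"), ], path,
                   row.names = FALSE)
  invisible(path)
}
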