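#' Empirical (resampled) summary table
#'
#' One nine-statistic row per metric (or per gain covariate), computed from
#' the archived replicates.
#'
#' @param archive A `replicate_archive`.
#' @param what `"metrics"` or `"gains"`.
#' @param round_digits Decimals for the printed table (default 3); `NULL`
#'   keeps full precision.
#' @return Data frame with a label column (`Metrics` or `Covariates`) and the
#'   ten statistic columns `Minimum, 5th Percentile, 25th Percentile, Median,
#'   75th Percentile, 95th Percentile, Maximum, Mean, SD, Range`.
#' @export
build_bootstrap_table <- function(archive, what = c("metrics", "gains"),
                                  round_digits = 3) {
  what <- match.arg(what)
  block <- summary_block(archive, what)
  rows <- lapply(names(block), function(nm) {
    x <- block[[nm]]
    if (all(is.na(x))) return(NULL)
    summary_row(nm, suppressWarnings(empirical_summary(x, round_digits)), what)
  })
  assemble_table(rows, what)
}

#' Analytic (ADD) summary table
#'
#' For each metric (or gain covariate): the point estimate is the mean of the
#' archived replicates; the variance is analytic — `p(1-p)/n` by default for
#' every column, or one of the AUROC-specific formulas for the AUROC row via
#' `auroc_method`. The minimum/maximum columns are clamped to the empirical
#' min/max of the companion resampling run (the convention of the published
#' tables); the quantiles in between are closed-form Gaussian.
#'
#' Applying the proportion formula to balanced accuracy and to gain shares is
#' an extrapolation beyond the metrics for which it was proposed; rows are
#' produced all the same and the vignette discusses the caveat.
#'
#' @param archive A `replicate_archive`.
#' @param n_for_variance Sample size entering the variance formulas;
#'   defaults to the archived test-set size.
#' @param auroc_method Variance formula for the AUROC row: `"proportion"`
#'   (default), `"mann_whitney"` or `"large_n"`.
#' @inheritParams build_bootstrap_table
#' @return Data frame in the same layout as [build_bootstrap_table()].
#' @export
build_add_table <- function(archive, n_for_variance = NULL,
                            what = c("metrics", "gains"),
                            auroc_method = "proportion", round_digits = 3) {
  what <- match.arg(what)
  block <- summary_block(archive, what)
  if (is.null(n_for_variance)) {
    n_for_variance <- round(stats::median(archive$panels$n_test))
  }
  rows <- lapply(names(block), function(nm) {
    x <- block[[nm]]
    if (any(is.na(x))) {
      x <- x[!is.na(x)]
      if (length(x) < 2) return(NULL)
    }
    method <- if (nm == "auroc") auroc_method else "proportion"
    spec <- add_spec(mean(x), n_for_variance, method = method,
                     clamp = range(x))
    summary_row(nm, gaussian_quantile_summary(spec, round_digits), what)
  })
  assemble_table(rows, what)
}

summary_block <- function(archive, what) {
  stopifnot(inherits(archive, "replicate_archive"))
  if (what == "gains") {
    if (is.null(archive$gains)) {
      stop("archive has no gain vectors (adapter reports none)", call. = FALSE)
    }
    archive$gains
  } else {
    archive$panels[metric_names()]
  }
}

table_stat_names <- function() {
  c("Minimum", "5th Percentile", "25th Percentile", "Median",
    "75th Percentile", "95th Percentile", "Maximum", "Mean", "SD", "Range")
}

display_label <- function(nm) {
  pretty <- c(accuracy = "Accuracy", f1 = "F1", sensitivity = "Sensitivity",
              specificity = "Specificity", ppv = "PPV", npv = "NPV",
              balanced_accuracy = "Balanced accuracy", auroc = "AUROC",
              age = "Age", sex = "Sex", resting_bp = "Resting blood pressure",
              cholesterol = "Cholesterol", fasting_bs = "Fasting blood sugar",
              resting_ecg = "RestingECG", angina = "Angina",
              max_hr = "Maximum heart rate")
  ifelse(nm %in% names(pretty), pretty[nm], nm)
}

summary_row <- function(nm, qs, what) {
  row <- as.data.frame(as.list(unclass(qs)))
  names(row) <- table_stat_names()
  label <- data.frame(x = display_label(nm))
  names(label) <- if (what == "gains") "Covariates" else "Metrics"
  cbind(label, row)
}

assemble_table <- function(rows, what) {
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0) stop("no summarizable columns", call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a summary table CSV with the canonical header
#'
#' @param table Output of [build_bootstrap_table()] / [build_add_table()].
#' @param path CSV path.
#' @export
write_summary_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Compare an analytic and a resampled summary row
#'
#' Reports the SD ratio (analytic / resampled) and per-quantile absolute
#' differences, and flags the pair "similar" when every inner quantile (5th
#' through 95th) differs by less than `2 * boot_sd / sqrt(n_replicates) +
#' 0.005` — twice the Monte-Carlo standard error of the resampled mean plus
#' a small absolute floor. A heuristic screen, not a formal test.
#'
#' @param bootstrap,add `quantile_summary` rows for the same quantity.
#' @param n_replicates Replicates behind the resampled row (for the
#'   tolerance); `Inf` reduces the tolerance to the 0.005 floor.
#' @param label Optional row label.
#' @return A `comparison_row`: list with `label`, `sd_ratio`,
#'   `quantile_abs_diff` (named vector over p5..p95), `max_abs_diff`,
#'   `similar`.
#' @export
compare_distributions <- function(bootstrap, add, n_replicates = Inf,
                                  label = NA_character_) {
  stopifnot(inherits(bootstrap, "quantile_summary"),
            inherits(add, "quantile_summary"))
  inner <- c("p5", "p25", "median", "p75", "p95")
  diffs <- abs(unclass(add)[inner] - unclass(bootstrap)[inner])
  tol <- 2 * unname(bootstrap["sd"]) / sqrt(n_replicates) + 0.005
  structure(list(
    label = label,
    sd_ratio = unname(add["sd"] / bootstrap["sd"]),
    quantile_abs_diff = diffs,
    max_abs_diff = max(diffs),
    similar = all(diffs < tol)
  ), class = "comparison_row")
}

#' @export
print.comparison_row <- function(x, ...) {
  cat(sprintf("%s: sd ratio (ADD/resampled) = %.3f, max |quantile diff| = %.4f, %s\n",
              if (is.na(x$label)) "comparison" else x$label,
              x$sd_ratio, x$max_abs_diff,
              if (x$similar) "similar" else "NOT similar"))
  invisible(x)
}

#' Aggregate model ranking across metric means
#'
#' Ranks each model on each metric's replicate mean (higher is better) and
#' averages the ranks. This mean-rank aggregate is this package's own
#' definition of "best across several metrics"; no standard definition
#' exists, so treat it as a screening device.
#'
#' @param archives Named list of `replicate_archive`s (one per model).
#' @param metrics Metrics entering the aggregate (default: all eight).
#' @return Data frame with `model`, `mean_rank` (1 = best) and the per-metric
#'   means, ordered best first.
#' @export
best_model_rank <- function(archives, metrics = metric_names()) {
  stopifnot(is.list(archives), !is.null(names(archives)))
  means <- sapply(archives, function(a) {
    colMeans(a$panels[metrics], na.rm = TRUE)
  })  # metrics x models
  ranks <- apply(-means, 1, rank)  # models x metrics; rank 1 = best
  out <- data.frame(model = names(archives), mean_rank = rowMeans(ranks),
                    t(means))
  out[order(out$mean_rank), ]
}

#' Histogram of replicate values with the ADD density overlaid
#'
#' A plain frequency-scaled histogram of the resampled values, with the
#' analytic Gaussian density drawn on top.
#'
#' @param values Replicate values of one metric.
#' @param spec The matching `add_spec`.
#' @param main Plot title.
#' @param ... Passed to [graphics::hist()].
#' @export
plot_add_histogram <- function(values, spec, main = NULL, ...) {
  stopifnot(inherits(spec, "add_spec"))
  graphics::hist(values, freq = FALSE, main = main, xlab = "metric value", ...)
  if (spec$sd > 0) {
    xs <- seq(min(values), max(values), length.out = 256)
    graphics::lines(xs, stats::dnorm(xs, spec$point_estimate, spec$sd), lwd = 2)
  } else {
    graphics::abline(v = spec$point_estimate, lwd = 2)
  }
  invisible(NULL)
}
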