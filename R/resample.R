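#' Plan for Monte-Carlo train/test re-splitting
#'
#' The "bootstrap simulation" of this workflow: the cohort is repeatedly
#' re-partitioned into train and test sets (70:30 by default), the model is
#' refit on each train set, and metrics are computed on the held-out test
#' set. This is Monte-Carlo cross-validation ("permuting the train-test
#' sets"), not resampling with replacement; a classical with-replacement
#' mode (`mode = "resample"`) is available for comparison, in which both
#' train and test rows are drawn i.i.d. with replacement from the cohort.
#'
#' @param n_replicates Number of replicates (the reference workflow uses
#'   10,000; scale down for interactive work).
#' @param train_fraction Fraction of rows in the train set, in (0, 1).
#'   Default 0.70; `|train| = round(train_fraction * N)`.
#' @param master_seed Integer master seed. Per-replicate seeds are derived
#'   from it by a counter scheme, so replicates are order-insensitive and a
#'   run is bit-reproducible.
#' @param stratified If `TRUE`, split within outcome classes so class
#'   proportions are preserved within one subject. Default `FALSE`.
#' @param mode `"split"` (default, disjoint re-partition) or `"resample"`
#'   (with replacement).
#' @return A `split_plan` object.
#' @export
split_plan <- function(n_replicates, train_fraction = 0.7, master_seed = 1L,
                       stratified = FALSE, mode = c("split", "resample")) {
  mode <- match.arg(mode)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("`train_fraction` must be in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(n_replicates) || n_replicates < 1) {
    stop("`n_replicates` must be >= 1", call. = FALSE)
  }
  structure(list(
    n_replicates = as.integer(n_replicates),
    train_fraction = train_fraction,
    master_seed = as.integer(master_seed),
    stratified = isTRUE(stratified),
    mode = mode
  ), class = "split_plan")
}

# counter-based substream: deterministic in (master, index, attempt),
# exact in double arithmetic (values stay far below 2^53)
replicate_seed <- function(master_seed, index, attempt = 0) {
  as.integer((abs(as.double(master_seed)) + index * 1000003 + attempt * 7919) %%
               2147483629) + 1L
}

#' Draw one train/test partition
#'
#' Deterministic given `(plan$master_seed, index)`. In `"split"` mode the
#' partition is disjoint and exhaustive with `|train| = round(f * N)`. A draw
#' that leaves either outcome class absent from train or test is rejected and
#' redrawn from a fresh substream; the number of rejections is returned in
#' the `rejected` field.
#'
#' @param data Cohort table with an `outcome` column and >= 10 rows.
#' @param plan A `split_plan`.
#' @param index Replicate index (1-based).
#' @param outcome Name of the 0/1 outcome column.
#' @return List with integer row indices `train`, `test`, and a `rejected`
#'   count.
#' @export
permute_split <- function(data, plan, index, outcome = "outcome") {
  stopifnot(inherits(plan, "split_plan"))
  n <- nrow(data)
  if (n < 10) stop("need at least 10 rows to split", call. = FALSE)
  y <- data[[outcome]]
  if (is.null(y) || !all(y %in% c(0, 1))) {
    stop("`", outcome, "` must be a 0/1 column", call. = FALSE)
  }
  n_train <- round(plan$train_fraction * n)

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old), add = TRUE)

  for (attempt in 0:100) {
    set.seed(replicate_seed(plan$master_seed, index, attempt))
    if (plan$mode == "resample") {
      train <- sample.int(n, n_train, replace = TRUE)
      test <- sample.int(n, n - n_train, replace = TRUE)
    } else if (plan$stratified) {
      idx1 <- which(y == 1); idx0 <- which(y == 0)
      k1 <- round(plan$train_fraction * length(idx1))
      k0 <- n_train - k1
      train <- c(sample(idx1, k1), sample(idx0, k0))
      test <- setdiff(seq_len(n), train)
    } else {
      train <- sample.int(n, n_train)
      test <- setdiff(seq_len(n), train)
    }
    ok <- length(unique(y[train])) == 2 && length(unique(y[test])) == 2
    if (ok) {
      return(list(train = sort(train), test = sort(test), rejected = attempt))
    }
  }
  stop("could not draw a split with both classes in train and test after ",
       "100 attempts", call. = FALSE)
}

#' Run the resampling engine
#'
#' For each replicate: draw a partition, fit the adapter on the train rows,
#' score the test rows, archive the metric panel (and the normalized gain
#' vector when the adapter reports gain). Adapter failures are caught,
#' logged and skipped; if more than 5\% of replicates fail the run errors.
#'
#' @param data Cohort table with an `outcome` column.
#' @param plan A `split_plan`.
#' @param adapter A `model_adapter`.
#' @param outcome Outcome column name.
#' @param cutoff Classification threshold for the confusion-matrix metrics.
#' @return A `replicate_archive`: list with `panels` (data frame, one row per
#'   replicate, columns = the eight metrics + `n_test`), `gains` (data frame
#'   or `NULL`), `seeds`, `plan`, `adapter_name`, `cutoff`, `n_rows`,
#'   `n_rejected_splits`, `n_failed`.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_rows = 120, seed = 3))
#' arch <- run_replicates(cohort, split_plan(20, master_seed = 3),
#'                        oracle_adapter(cohort))
#' colMeans(arch$panels[, c("accuracy", "auroc")])
#' @export
run_replicates <- function(data, plan, adapter, outcome = "outcome",
                           cutoff = 0.5) {
  stopifnot(inherits(plan, "split_plan"), inherits(adapter, "model_adapter"))
  R <- plan$n_replicates
  panel_cols <- c(metric_names(), "n_test")
  panels <- matrix(NA_real_, nrow = R, ncol = length(panel_cols),
                   dimnames = list(NULL, panel_cols))
  gains <- NULL
  seeds <- integer(R)
  n_rejected <- 0L
  failed <- logical(R)

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old), add = TRUE)

  for (i in seq_len(R)) {
    sp <- permute_split(data, plan, i, outcome = outcome)
    n_rejected <- n_rejected + sp$rejected
    # model-fitting substream disjoint from the split substreams (attempts 0..100)
    seeds[i] <- replicate_seed(plan$master_seed, i, attempt = 101L)
    res <- tryCatch({
      set.seed(seeds[i])  # adapter-internal randomness shares the substream
      fit <- adapter$fit(data[sp$train, , drop = FALSE])
      test <- data[sp$test, , drop = FALSE]
      scores <- adapter$predict_scores(fit, test)
      panel <- suppressWarnings(metric_panel(test[[outcome]], scores, cutoff))
      g <- if (!is.null(adapter$feature_gain)) {
        normalize_gain(adapter$feature_gain(fit))
      }
      list(panel = panel, gain = g)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed[i] <- TRUE
      next
    }
    panels[i, ] <- unlist(res$panel[panel_cols])
    if (!is.null(res$gain)) {
      if (is.null(gains)) {
        gains <- matrix(NA_real_, nrow = R, ncol = length(res$gain),
                        dimnames = list(NULL, names(res$gain)))
      }
      gains[i, names(res$gain)] <- res$gain
    }
  }

  if (any(failed)) {
    if (mean(failed) > 0.05) {
      stop(sprintf("adapter failed on %d/%d replicates (> 5%%)", sum(failed), R),
           call. = FALSE)
    }
    warning(sprintf("adapter failed on %d/%d replicates; skipped", sum(failed), R),
            call. = FALSE)
  }

  keep <- !failed
  structure(list(
    panels = as.data.frame(panels[keep, , drop = FALSE]),
    gains = if (!is.null(gains)) as.data.frame(gains[keep, , drop = FALSE]),
    seeds = seeds[keep],
    plan = plan,
    adapter_name = adapter$name,
    outcome = outcome,
    cutoff = cutoff,
    n_rows = nrow(data),
    n_rejected_splits = n_rejected,
    n_failed = sum(failed)
  ), class = "replicate_archive")
}

#' @export
print.replicate_archive <- function(x, ...) {
  cat(sprintf("Replicate archive: %d replicates, adapter '%s', %d rows (%s mode)\n",
              nrow(x$panels), x$adapter_name, x$n_rows, x$plan$mode))
  cat("Metric means:\n")
  print(round(colMeans(x$panels[, metric_names()], na.rm = TRUE), 3))
  invisible(x)
}

#' Normalize a raw gain vector to sum to 1
#'
#' @param raw_gains Named non-negative vector with at least one positive
#'   entry.
#' @return The vector scaled to sum to 1, order preserved.
#' @export
normalize_gain <- function(raw_gains) {
  if (any(raw_gains < 0) || any(!is.finite(raw_gains))) {
    stop("gains must be finite and non-negative", call. = FALSE)
  }
  total <- sum(raw_gains)
  if (total == 0) stop("all-zero gain vector cannot be normalized", call. = FALSE)
  raw_gains / total
}

#' Write / read a replicate archive as CSV
#'
#' One row per replicate: `replicate`, `seed`, the eight metrics, `n_test`,
#' and one `gain_<covariate>` column per covariate when gain was archived.
#' Summaries are recomputable from the CSV without refitting any model.
#'
#' @param archive A `replicate_archive`.
#' @param path CSV file path.
#' @export
write_archive <- function(archive, path) {
  stopifnot(inherits(archive, "replicate_archive"))
  tab <- data.frame(replicate = seq_len(nrow(archive$panels)),
                    seed = archive$seeds, archive$panels)
  if (!is.null(archive$gains)) {
    g <- archive$gains
    names(g) <- paste0("gain_", names(g))
    tab <- cbind(tab, g)
  }
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_archive
#' @return `read_archive()` returns a `replicate_archive` (with `plan` set to
#'   `NULL`: the CSV stores results, not the plan).
#' @export
read_archive <- function(path) {
  tab <- utils::read.csv(path)
  gain_cols <- grep("^gain_", names(tab), value = TRUE)
  panel_cols <- c(metric_names(), "n_test")
  missing_cols <- setdiff(panel_cols, names(tab))
  if (length(missing_cols) > 0) {
    stop("archive CSV is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  gains <- if (length(gain_cols) > 0) {
    g <- tab[gain_cols]
    names(g) <- sub("^gain_", "", names(g))
    g
  }
  structure(list(
    panels = tab[panel_cols],
    gains = gains,
    seeds = tab$seed,
    plan = NULL,
    adapter_name = NA_character_,
    outcome = "outcome",
    cutoff = NA_real_,
    n_rows = NA_integer_,
    n_rejected_splits = NA_integer_,
    n_failed = NA_integer_
  ), class = "replicate_archive")
}
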