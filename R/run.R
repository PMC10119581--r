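#' Run the full comparison workflow and write its artifacts
#'
#' Orchestrates one experiment: obtain a cohort (a synthetic preset or a
#' user-supplied CSV), run the resampling engine with the chosen model
#' adapter, and write to `out_dir`:
#' \itemize{
#'   \item `archive.csv` — per-replicate metric panels (and gain vectors),
#'   \item `metrics_bootstrap.csv` / `metrics_add.csv` — resampled vs
#'     analytic metric summary tables,
#'   \item `gain_bootstrap.csv` / `gain_add.csv` — idem for gain (when the
#'     adapter reports gain),
#'   \item `ad_report.csv` — Anderson-Darling sufficiency report,
#'   \item `manifest.json` — the full configuration; rerunning from it
#'     reproduces every CSV byte for byte,
#'   \item optional `hist_<metric>.png` histograms (`plots = TRUE`).
#' }
#'
#' @param out_dir Output directory (created if absent).
#' @param cohort_csv Path to a cohort CSV, or `NULL` to generate a synthetic
#'   cohort.
#' @param synthetic Synthetic preset when `cohort_csv` is `NULL`:
#'   `"paper-like"` (918 rows, prevalence 0.55, strong signal) or `"null"`
#'   (no signal).
#' @param adapter Adapter name (see [get_adapter()]).
#' @param n_replicates,train_fraction,stratified,mode Passed to
#'   [split_plan()].
#' @param seed Master seed for the cohort and the engine.
#' @param cutoff Classification threshold.
#' @param n_for_variance Sample size for the analytic variances (default:
#'   the test-set size).
#' @param auroc_method AUROC variance formula for the ADD table.
#' @param plots Write PNG histograms (default `FALSE`; PNG output is not
#'   covered by the byte-reproducibility contract).
#' @return Invisibly, a list with the archive, the four tables, the AD
#'   report and the manifest path.
#' @export
run_analysis <- function(out_dir,
                         cohort_csv = NULL,
                         synthetic = c("paper-like", "null"),
                         adapter = "xgboost",
                         n_replicates = 200,
                         train_fraction = 0.7,
                         stratified = FALSE,
                         mode = "split",
                         seed = 1L,
                         cutoff = 0.5,
                         n_for_variance = NULL,
                         auroc_method = "proportion",
                         plots = FALSE) {
  synthetic <- match.arg(synthetic)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  cohort <- if (!is.null(cohort_csv)) {
    read_cohort(cohort_csv)
  } else if (synthetic == "null") {
    generate_cohort(null_cohort_spec(seed = seed))
  } else {
    generate_cohort(cohort_spec(seed = seed))
  }
  if (adapter == "oracle" && !is.null(cohort_csv)) {
    stop("the oracle adapter needs a generated cohort, not a CSV", call. = FALSE)
  }

  plan <- split_plan(n_replicates, train_fraction = train_fraction,
                     master_seed = seed, stratified = stratified, mode = mode)
  archive <- run_replicates(cohort, plan, get_adapter(adapter, cohort),
                            cutoff = cutoff)
  write_archive(archive, file.path(out_dir, "archive.csv"))

  tables <- summarize_archive(archive, out_dir, n_for_variance = n_for_variance,
                              auroc_method = auroc_method)
  report <- sufficiency_report(archive)
  write_sufficiency_csv(report, file.path(out_dir, "ad_report.csv"))

  if (plots) write_histograms(archive, out_dir, n_for_variance)

  manifest <- list(
    tool = "addmetrics", version = as.character(utils::packageVersion("addmetrics")),
    cohort_csv = cohort_csv, synthetic = if (is.null(cohort_csv)) synthetic,
    adapter = adapter, n_replicates = n_replicates,
    train_fraction = train_fraction, stratified = stratified, mode = mode,
    seed = seed, cutoff = cutoff, n_for_variance = n_for_variance,
    auroc_method = auroc_method
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, null = "null",
                       pretty = TRUE)
  invisible(list(archive = archive, tables = tables, ad_report = report,
                 manifest = manifest_path))
}

summarize_archive <- function(archive, out_dir, n_for_variance = NULL,
                              auroc_method = "proportion") {
  tables <- list(
    metrics_bootstrap = build_bootstrap_table(archive, "metrics"),
    metrics_add = build_add_table(archive, n_for_variance, "metrics",
                                  auroc_method = auroc_method)
  )
  if (!is.null(archive$gains)) {
    tables$gain_bootstrap <- build_bootstrap_table(archive, "gains")
    tables$gain_add <- build_add_table(archive, n_for_variance, "gains")
  }
  for (nm in names(tables)) {
    write_summary_csv(tables[[nm]], file.path(out_dir, paste0(nm, ".csv")))
  }
  tables
}

write_histograms <- function(archive, out_dir, n_for_variance = NULL) {
  if (!requireNamespace("grDevices", quietly = TRUE)) return(invisible(NULL))
  if (is.null(n_for_variance)) {
    n_for_variance <- round(stats::median(archive$panels$n_test))
  }
  for (nm in metric_names()) {
    x <- archive$panels[[nm]]
    if (any(is.na(x)) || stats::sd(x) == 0) next
    spec <- add_spec(mean(x), n_for_variance)
    grDevices::png(file.path(out_dir, paste0("hist_", nm, ".png")),
                   width = 640, height = 480)
    plot_add_histogram(x, spec, main = display_label(nm))
    grDevices::dev.off()
  }
  invisible(NULL)
}

#' Rerun an analysis from its manifest
#'
#' Reads `manifest.json` written by [run_analysis()] and repeats the run.
#' All CSV artifacts are byte-identical to the original run's.
#'
#' @param manifest_path Path to a manifest JSON.
#' @param out_dir Output directory for the rerun.
#' @return See [run_analysis()].
#' @export
rerun_manifest <- function(manifest_path, out_dir) {
  m <- jsonlite::read_json(manifest_path)
  run_analysis(
    out_dir = out_dir,
    cohort_csv = m$cohort_csv,
    synthetic = if (is.null(m$synthetic)) "paper-like" else m$synthetic,
    adapter = m$adapter,
    n_replicates = m$n_replicates,
    train_fraction = m$train_fraction,
    stratified = isTRUE(m$stratified),
    mode = m$mode,
    seed = m$seed,
    cutoff = m$cutoff,
    n_for_variance = m$n_for_variance,
    auroc_method = m$auroc_method
  )
}
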