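make_archive <- function(n_rows = 400, R = 200, seed = 15) {
  co <- tiny_cohort(n = n_rows, seed = seed)
  run_replicates(co, split_plan(R, master_seed = seed), oracle_adapter(co))
}

test_that("summary tables carry the canonical column header, in order", {
  arch <- make_archive(R = 50)
  boot <- build_bootstrap_table(arch)
  add <- build_add_table(arch)
  header <- c("Metrics", "Minimum", "5th Percentile", "25th Percentile",
              "Median", "75th Percentile", "95th Percentile", "Maximum",
              "Mean", "SD", "Range")
  expect_identical(names(boot), header)
  expect_identical(names(add), header)

  f <- tempfile(fileext = ".csv")
  write_summary_csv(boot, f)
  expect_identical(
    readLines(f, n = 1),
    paste0('"', paste(header, collapse = '","'), '"')
  )
})

test_that("every written number round-trips through the CSV", {
  arch <- make_archive(R = 50)
  add <- build_add_table(arch)
  f <- tempfile(fileext = ".csv")
  write_summary_csv(add, f)
  back <- utils::read.csv(f, check.names = FALSE)
  expect_equal(back, add, tolerance = 0)
})

test_that("the ADD table clamps its extremes to the resampled min/max", {
  arch <- make_archive()
  boot <- build_bootstrap_table(arch, round_digits = NULL)
  add <- build_add_table(arch, round_digits = NULL)
  expect_equal(add$Minimum, boot$Minimum, tolerance = 1e-12)
  expect_equal(add$Maximum, boot$Maximum, tolerance = 1e-12)
  # means agree by construction; percentiles are Gaussian around them
  expect_equal(add$Mean, boot$Mean, tolerance = 1e-12)
})

test_that("ADD table rows reproduce the closed-form Gaussian quantiles", {
  # row format check against hand-computed cells: mean 0.789, sd 0.024
  qs <- gaussian_quantile_summary(
    add_spec(0.789, round(0.789 * (1 - 0.789) / 0.024^2)), round_digits = 3)
  expect_equal(unname(qs["p25"]), 0.773)
  expect_equal(unname(qs["p75"]), 0.805)
  # gain-style row: mean 0.24, sd 0.025
  qs <- gaussian_quantile_summary(
    add_spec(0.24, round(0.24 * 0.76 / 0.025^2)), round_digits = 3)
  expect_equal(unname(qs["p5"]), 0.199)
  expect_equal(unname(qs["p95"]), 0.281)
})

test_that("AUROC variance method flag reaches the AUROC row only", {
  arch <- make_archive(R = 100)
  n <- arch$panels$n_test[1]
  add_mw <- build_add_table(arch, auroc_method = "mann_whitney",
                            round_digits = NULL)
  a_mean <- mean(arch$panels$auroc)
  i <- which(add_mw$Metrics == "AUROC")
  expect_equal(add_mw$SD[i], sqrt(var_auroc_mann_whitney(n)), tolerance = 1e-12)
  j <- which(add_mw$Metrics == "Accuracy")
  expect_equal(add_mw$SD[j],
               sqrt(var_proportion(mean(arch$panels$accuracy), n)),
               tolerance = 1e-12)
})

test_that("compare_distributions flags identity and halved sd correctly", {
  qs <- gaussian_quantile_summary(add_spec(0.8, 300))
  cmp <- compare_distributions(qs, qs)
  expect_equal(cmp$sd_ratio, 1)
  expect_equal(cmp$max_abs_diff, 0)
  expect_true(cmp$similar)

  half <- gaussian_quantile_summary(add_spec(0.8, 1200))
  cmp <- compare_distributions(qs, half)
  expect_equal(cmp$sd_ratio, 0.5, tolerance = 1e-12)
  expect_false(cmp$similar)  # p5/p95 shift by ~0.019 >> tolerance
})

test_that("analytic and resampled distributions are similar on a closed loop", {
  arch <- make_archive(n_rows = 918, R = 500, seed = 23)
  n <- arch$panels$n_test[1]
  x <- arch$panels$accuracy
  boot <- empirical_summary(x)
  add <- gaussian_quantile_summary(add_spec(mean(x), n, clamp = range(x)))
  cmp <- compare_distributions(boot, add, n_replicates = 500)
  # generous similarity scale: quantile gaps stay within ~half the sd
  expect_lt(cmp$max_abs_diff, 0.5 * boot[["sd"]])
})

test_that("gain rows: the proportion-formula sd exceeds the resampled gain sd for most covariates", {
  skip_if_not_installed("xgboost")
  co <- tiny_cohort(n = 400, seed = 24)
  arch <- run_replicates(co, split_plan(60, master_seed = 24),
                         xgboost_adapter(nrounds = 20))
  boot <- build_bootstrap_table(arch, "gains", round_digits = NULL)
  add <- build_add_table(arch, what = "gains", round_digits = NULL)
  expect_identical(names(boot)[1], "Covariates")
  # gain shares are not proportions of n_test independent subjects, so
  # p(1-p)/n_test overstates their refit-to-refit variability for most
  # covariates — the direction the published gain tables show as well
  expect_gt(mean(add$SD > boot$SD), 0.5)
})

test_that("best_model_rank averages per-metric ranks", {
  arch_good <- make_archive(R = 30, seed = 25)
  arch_bad <- arch_good
  cols <- c("accuracy", "f1", "sensitivity", "specificity", "ppv", "npv",
            "balanced_accuracy", "auroc")
  arch_bad$panels[cols] <- arch_good$panels[cols] * 0.8
  ranking <- best_model_rank(list(good = arch_good, bad = arch_bad))
  expect_equal(ranking$model[1], "good")
  expect_equal(ranking$mean_rank, c(1, 2))
})

test_that("degenerate metrics produce a flagged, zero-sd ADD row", {
  arch <- make_archive(R = 30, seed = 26)
  arch$panels$accuracy <- 1  # all replicates identical at the boundary
  add <- build_add_table(arch, round_digits = NULL)
  i <- which(add$Metrics == "Accuracy")
  expect_equal(add$SD[i], 0)
  expect_equal(add$Median[i], 1)
})
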