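test_that("permute_split partitions with the documented arithmetic", {
  co <- tiny_cohort(n = 120)
  plan <- split_plan(5, master_seed = 4)

  sp <- permute_split(co[1:10, ], plan, 1)
  expect_length(sp$train, 7)
  expect_length(sp$test, 3)
  expect_setequal(c(sp$train, sp$test), 1:10)

  big <- tiny_cohort(n = 918, seed = 21)
  sp <- permute_split(big, plan, 1)
  expect_length(sp$train, 643)  # round(0.7 * 918)
  expect_length(sp$test, 275)
  expect_length(intersect(sp$train, sp$test), 0)
})

test_that("splits are deterministic in (master_seed, index)", {
  co <- tiny_cohort()
  plan <- split_plan(5, master_seed = 99)
  expect_identical(permute_split(co, plan, 3), permute_split(co, plan, 3))
  expect_false(identical(permute_split(co, plan, 3)$train,
                         permute_split(co, plan, 4)$train))
  plan2 <- split_plan(5, master_seed = 100)
  expect_false(identical(permute_split(co, plan, 3)$train,
                         permute_split(co, plan2, 3)$train))
})

test_that("stratified splits preserve class proportions within one subject", {
  co <- tiny_cohort(n = 301, seed = 6)
  plan <- split_plan(5, master_seed = 1, stratified = TRUE)
  for (i in 1:5) {
    sp <- permute_split(co, plan, i)
    n1_train <- sum(co$outcome[sp$train])
    expect_lte(abs(n1_train - 0.7 * sum(co$outcome)), 1)
    expect_length(sp$train, round(0.7 * 301))
  }
})

test_that("splits leaving a class absent are rejected and redrawn", {
  co <- tiny_cohort(n = 40, seed = 2)
  co$outcome <- c(1, 1, rep(0, 38))  # only two events: rejections are likely
  plan <- split_plan(50, master_seed = 12)
  rejections <- vapply(1:50, function(i) {
    sp <- permute_split(co, plan, i)
    y_train <- co$outcome[sp$train]; y_test <- co$outcome[sp$test]
    expect_true(all(c(0, 1) %in% y_train) && all(c(0, 1) %in% y_test))
    sp$rejected
  }, numeric(1))
  expect_gt(sum(rejections), 0)
})

test_that("run_replicates archives one panel per replicate, reproducibly", {
  co <- tiny_cohort()
  plan <- split_plan(25, master_seed = 7)
  a1 <- run_replicates(co, plan, oracle_adapter(co))
  a2 <- run_replicates(co, plan, oracle_adapter(co))
  expect_identical(a1$panels, a2$panels)
  expect_identical(a1$seeds, a2$seeds)
  expect_equal(nrow(a1$panels), 25)
  expect_equal(length(a1$seeds), 25)
  expect_true(all(a1$panels$n_test == 120 - round(0.7 * 120)))
})

test_that("a perfect-knowledge adapter scores 1 on every panel", {
  co <- tiny_cohort()
  arch <- run_replicates(co, split_plan(10, master_seed = 3), perfect_adapter())
  expect_true(all(arch$panels$auroc == 1))
  expect_true(all(arch$panels$accuracy == 1))
  expect_true(all(arch$panels$f1 == 1))
})

test_that("a no-signal adapter averages AUROC 1/2", {
  co <- tiny_cohort(n = 400, seed = 13)
  arch <- run_replicates(co, split_plan(500, master_seed = 13), null_adapter())
  expect_lt(abs(mean(arch$panels$auroc) - 0.5), 0.02)
})

test_that("no test row ever appears in its own training set", {
  co <- tiny_cohort(n = 80, seed = 4)
  plan <- split_plan(40, master_seed = 5)
  for (i in seq_len(plan$n_replicates)) {
    sp <- permute_split(co, plan, i)
    expect_length(intersect(sp$train, sp$test), 0)
    expect_setequal(c(sp$train, sp$test), seq_len(80))
  }
})

test_that("normalize_gain scales to unit sum and keeps order", {
  expect_equal(normalize_gain(c(a = 2, b = 2)), c(a = 0.5, b = 0.5))
  expect_equal(normalize_gain(c(a = 1, b = 0, c = 3)), c(a = 0.25, b = 0, c = 0.75))
  g <- c(u = 0.3, v = 1.2, w = 0.1, x = 2, y = 0, z = 0.4, q = 1, r = 0.05)
  expect_equal(normalize_gain(g * 17.3), normalize_gain(g))
  expect_equal(sum(normalize_gain(g)), 1, tolerance = 1e-12)
  expect_error(normalize_gain(c(a = 0, b = 0)), "all-zero")
  expect_error(normalize_gain(c(a = -1, b = 2)), "non-negative")
})

test_that("gain vectors are archived normalized, one entry per covariate", {
  skip_if_not_installed("xgboost")
  co <- tiny_cohort(n = 150, seed = 8)
  arch <- run_replicates(co, split_plan(5, master_seed = 8),
                         xgboost_adapter(nrounds = 15))
  expect_equal(sort(names(arch$gains)),
               sort(setdiff(names(co), "outcome")))
  expect_true(all(abs(rowSums(arch$gains) - 1) < 1e-12))
  expect_true(all(arch$gains >= 0))
})

test_that("failing adapters are skipped below 5% and fatal above", {
  co <- tiny_cohort(n = 100, seed = 5)
  flaky <- function(fail_on) {
    model_adapter("flaky",
      fit = function(data) NULL,
      predict_scores = local({
        calls <- 0
        function(fit, newdata) {
          calls <<- calls + 1
          if (calls %in% fail_on) stop("boom")
          rep(0.5, nrow(newdata)) + newdata$outcome * 0.1
        }
      })
    )
  }
  expect_warning(arch <- run_replicates(co, split_plan(100, master_seed = 1),
                                        flaky(3)), "failed on 1/100")
  expect_equal(nrow(arch$panels), 99)
  expect_equal(arch$n_failed, 1)
  expect_error(
    suppressWarnings(run_replicates(co, split_plan(20, master_seed = 1), flaky(1:3))),
    "> 5%"
  )
})

test_that("archives round-trip through CSV without refitting", {
  skip_if_not_installed("xgboost")
  co <- tiny_cohort(n = 150, seed = 9)
  arch <- run_replicates(co, split_plan(6, master_seed = 9),
                         xgboost_adapter(nrounds = 10))
  f <- tempfile(fileext = ".csv")
  write_archive(arch, f)
  back <- read_archive(f)
  expect_equal(back$panels, arch$panels, tolerance = 1e-12)
  expect_equal(back$gains, arch$gains, tolerance = 1e-12)
  expect_equal(back$seeds, arch$seeds)
})

test_that("with i.i.d. test draws a fixed scorer's accuracy sd matches p(1-p)/n", {
  co <- tiny_cohort(n = 918, seed = 31)
  # fixed rule, no refitting; "resample" mode draws test rows i.i.d., so the
  # number of correct calls is binomial and sd(accuracy) -> sqrt(p(1-p)/n)
  plan <- split_plan(2000, master_seed = 31, mode = "resample")
  arch <- run_replicates(co, plan, fixed_rule_adapter())
  p <- mean(arch$panels$accuracy)
  n_test <- arch$panels$n_test[1]
  expect_lt(abs(sd(arch$panels$accuracy) / sqrt(p * (1 - p) / n_test) - 1), 0.15)
})

test_that("re-splitting a fixed cohort shrinks the sd by the finite-population factor", {
  co <- tiny_cohort(n = 918, seed = 31)
  plan <- split_plan(2000, master_seed = 31)
  arch <- run_replicates(co, plan, fixed_rule_adapter())
  p <- mean(arch$panels$accuracy)
  n_test <- arch$panels$n_test[1]
  fpc <- sqrt((918 - n_test) / (918 - 1))  # sampling without replacement
  ratio <- sd(arch$panels$accuracy) / sqrt(p * (1 - p) / n_test)
  expect_lt(abs(ratio / fpc - 1), 0.10)
})
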