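#' Model adapter contract
#'
#' A model adapter plugs a classifier into the resampling engine. It is a
#' list of three functions plus a name:
#' \describe{
#'   \item{fit(data)}{trains on a table with covariate columns and a 0/1
#'     `outcome` column; returns an opaque fitted object.}
#'   \item{predict_scores(fit, newdata)}{returns scores in \[0, 1\], one per
#'     row of `newdata`; only ever called with the object `fit` returned.}
#'   \item{feature_gain(fit)}{returns a named non-negative vector with one
#'     entry per covariate (tree-ensemble gain importance), or `NULL` when
#'     the model has no gain notion (then no gain is archived — it is never
#'     imputed).}
#' }
#'
#' @param name Short adapter name (used in manifests and reports).
#' @param fit,predict_scores,feature_gain The three functions above
#'   (`feature_gain` may be `NULL`).
#' @return A `model_adapter` object.
#' @export
model_adapter <- function(name, fit, predict_scores, feature_gain = NULL) {
  stopifnot(is.character(name), is.function(fit), is.function(predict_scores),
            is.null(feature_gain) || is.function(feature_gain))
  structure(list(name = name, fit = fit, predict_scores = predict_scores,
                 feature_gain = feature_gain),
            class = "model_adapter")
}

#' @export
print.model_adapter <- function(x, ...) {
  cat("Model adapter:", x$name,
      if (is.null(x$feature_gain)) "(no gain)" else "(reports gain)", "\n")
  invisible(x)
}

#' Oracle adapter: the true generative scorer
#'
#' Returns the covariate-conditional event probability of the synthetic
#' generative model — the Bayes-optimal score. `fit` is a no-op, so this
#' adapter isolates pure train/test re-splitting variability from model
#' refitting variability.
#'
#' @param cohort A table from [generate_cohort()] (source of the generative
#'   parameters; any subset of its rows can then be scored).
#' @return A `model_adapter`.
#' @export
oracle_adapter <- function(cohort) {
  oracle <- attr(cohort, "oracle")
  if (is.null(oracle)) {
    stop("`cohort` must come from generate_cohort()", call. = FALSE)
  }
  model_adapter(
    name = "oracle",
    fit = function(data) oracle,
    predict_scores = function(fit, newdata) {
      oracle_scores(NULL, newdata = newdata, oracle = fit)
    }
  )
}

#' Null adapter: scores independent of the outcome
#'
#' Uniform random scores regenerated at each predict call (from the engine's
#' per-replicate RNG stream). True AUROC is 0.5 by exchangeability; useful as
#' a negative control.
#'
#' @return A `model_adapter`.
#' @export
null_adapter <- function() {
  model_adapter(
    name = "null",
    fit = function(data) NULL,
    predict_scores = function(fit, newdata) stats::runif(nrow(newdata))
  )
}

#' Logistic-regression adapter
#'
#' `stats::glm` with a binomial link on all covariate columns.
#'
#' @return A `model_adapter`.
#' @export
logistic_adapter <- function() {
  model_adapter(
    name = "logistic",
    fit = function(data) {
      stats::glm(outcome ~ ., data = data, family = stats::binomial())
    },
    predict_scores = function(fit, newdata) {
      unname(stats::predict(fit, newdata = newdata, type = "response"))
    }
  )
}

#' Gradient-boosted-trees adapter (XGBoost)
#'
#' Binary logistic objective on the raw covariate matrix. Fixed
#' hyperparameters per run (no per-replicate tuning). This is the adapter
#' whose per-feature gain importance feeds the gain tables.
#'
#' @param nrounds Boosting rounds (default 60).
#' @param params List of XGBoost parameters; defaults keep a single thread
#'   and modest depth/eta suited to cohorts of ~1000 rows.
#' @return A `model_adapter`.
#' @export
xgboost_adapter <- function(nrounds = 60, params = list()) {
  if (!requireNamespace("xgboost", quietly = TRUE)) {
    stop("the 'xgboost' package is required for xgboost_adapter()", call. = FALSE)
  }
  defaults <- list(objective = "binary:logistic", max_depth = 3, eta = 0.3,
                   nthread = 1)
  params <- utils::modifyList(defaults, params)
  model_adapter(
    name = "xgboost",
    fit = function(data) {
      x <- as.matrix(data[setdiff(names(data), "outcome")])
      booster <- xgboost::xgb.train(
        params = params,
        data = xgboost::xgb.DMatrix(x, label = data$outcome, nthread = 1),
        nrounds = nrounds, verbose = 0
      )
      list(booster = booster, features = colnames(x))
    },
    predict_scores = function(fit, newdata) {
      x <- as.matrix(newdata[setdiff(names(newdata), "outcome")])
      predict(fit$booster, xgboost::xgb.DMatrix(x, nthread = 1))
    },
    feature_gain = function(fit) {
      imp <- xgboost::xgb.importance(model = fit$booster)
      gains <- stats::setNames(numeric(length(fit$features)), fit$features)
      gains[imp$Feature] <- imp$Gain  # features never split on keep gain 0
      gains
    }
  )
}

#' Random-forest adapter
#'
#' `randomForest` probability machine on all covariates; class-1 votes are
#' the scores.
#'
#' @param ntree Number of trees (default 200).
#' @return A `model_adapter`.
#' @export
random_forest_adapter <- function(ntree = 200) {
  if (!requireNamespace("randomForest", quietly = TRUE)) {
    stop("the 'randomForest' package is required for random_forest_adapter()",
         call. = FALSE)
  }
  model_adapter(
    name = "random_forest",
    fit = function(data) {
      data$outcome <- factor(data$outcome, levels = c(0, 1))
      randomForest::randomForest(outcome ~ ., data = data, ntree = ntree)
    },
    predict_scores = function(fit, newdata) {
      unname(stats::predict(fit, newdata = newdata, type = "prob")[, "1"])
    }
  )
}

#' Look up a built-in adapter by name
#'
#' @param name One of `"oracle"`, `"null"`, `"logistic"`, `"xgboost"`,
#'   `"random_forest"`.
#' @param cohort Required for `"oracle"`.
#' @return A `model_adapter`.
#' @export
get_adapter <- function(name, cohort = NULL) {
  switch(name,
    oracle = oracle_adapter(cohort),
    null = null_adapter(),
    logistic = logistic_adapter(),
    xgboost = xgboost_adapter(),
    random_forest = random_forest_adapter(),
    stop("unknown adapter '", name, "'; available: oracle, null, logistic, ",
         "xgboost, random_forest", call. = FALSE)
  )
}
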