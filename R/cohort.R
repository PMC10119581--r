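#' Specification of a synthetic heart-disease-like cohort
#'
#' Describes a tabular cohort resembling routinely collected heart-disease
#' prediction data: demographic covariates (age, sex), clinical covariates
#' (resting blood pressure, cholesterol, fasting blood sugar, resting ECG,
#' exertional angina, maximum heart rate) and a binary clinician-diagnosed
#' outcome. The outcome follows a logistic model on standardized covariates,
#' so `coefficients` are scale-free log-odds per SD. The default preset is a
#' synthetic stand-in — not estimates from any real cohort — calibrated so
#' that the true-probability (oracle) scorer attains AUROC close to 0.85 at
#' prevalence 0.55, the operating point of published heart-disease models on
#' cohorts of this size.
#'
#' @param n_rows Number of subjects (>= 20). Default 918.
#' @param prevalence Target outcome prevalence in (0, 1). Default 0.55.
#' @param coefficients Named log-odds per standardized covariate. Names must
#'   be a subset of the eight covariates; omitted ones get 0.
#' @param noise_sd SD of an additive latent Gaussian noise term on the
#'   linear predictor (default 0: the covariates carry all the signal).
#' @param seed Integer seed; the generated table is fully reproducible.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_rows = 918,
                        prevalence = 0.55,
                        coefficients = default_coefficients(),
                        noise_sd = 0,
                        seed = 1L) {
  if (!is.numeric(n_rows) || n_rows < 20) stop("`n_rows` must be >= 20", call. = FALSE)
  if (prevalence <= 0 || prevalence >= 1) stop("`prevalence` must be in (0, 1)", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  covs <- covariate_names()
  if (is.null(names(coefficients)) || !all(names(coefficients) %in% covs)) {
    stop("`coefficients` must be named by covariates: ",
         paste(covs, collapse = ", "), call. = FALSE)
  }
  beta <- stats::setNames(numeric(length(covs)), covs)
  beta[names(coefficients)] <- coefficients
  structure(list(
    n_rows = as.integer(n_rows),
    prevalence = prevalence,
    coefficients = beta,
    noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

covariate_names <- function() {
  c("age", "sex", "resting_bp", "cholesterol", "fasting_bs",
    "resting_ecg", "angina", "max_hr")
}

#' @rdname cohort_spec
#' @export
default_coefficients <- function() {
  c(angina = 1.1, cholesterol = 1.0, max_hr = -0.9, age = 0.5,
    sex = 0.35, resting_bp = 0.3, fasting_bs = 0.25, resting_ecg = 0.2)
}

#' @rdname cohort_spec
#' @details `null_cohort_spec()` is the no-signal preset (all coefficients
#'   zero, prevalence 0.5), under which any scorer has true AUROC 0.5.
#' @export
null_cohort_spec <- function(n_rows = 918, seed = 1L) {
  spec <- cohort_spec(n_rows = n_rows, prevalence = 0.5, seed = seed)
  spec$coefficients[] <- 0
  spec
}

#' Generate a synthetic cohort table
#'
#' Draws covariates from clinically plausible marginals (age ~ N(54, 9) years
#' clipped to \[25, 80\]; resting blood pressure ~ N(132, 18) mmHg in
#' \[80, 210\]; cholesterol ~ N(246, 52) mg/dL in \[85, 600\]; maximum heart
#' rate ~ N(137, 23) bpm in \[60, 210\]; sex/angina/fasting blood sugar
#' Bernoulli(0.7/0.4/0.23); resting ECG ordinal 0/1/2 with probabilities
#' 0.6/0.3/0.1), standardizes them, forms the linear predictor
#' `intercept + sum(beta_k x_k) + noise`, solves the intercept numerically so
#' the expected prevalence matches the target, and draws the 0/1 outcome.
#'
#' The returned data frame carries an `oracle` attribute (intercept,
#' coefficients, standardization constants) used by [oracle_adapter()] to
#' score arbitrary subsets with the true generative probability.
#'
#' @param spec A `cohort_spec`.
#' @return A data frame with the eight covariate columns and `outcome`.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_rows = 200, seed = 7))
#' mean(cohort$outcome)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old), add = TRUE)
  set.seed(spec$seed)

  n <- spec$n_rows
  clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  tab <- data.frame(
    age         = clip(stats::rnorm(n, 54, 9), 25, 80),
    sex         = stats::rbinom(n, 1, 0.7),
    resting_bp  = clip(stats::rnorm(n, 132, 18), 80, 210),
    cholesterol = clip(stats::rnorm(n, 246, 52), 85, 600),
    fasting_bs  = stats::rbinom(n, 1, 0.23),
    resting_ecg = sample(0:2, n, replace = TRUE, prob = c(0.6, 0.3, 0.1)),
    angina      = stats::rbinom(n, 1, 0.4),
    max_hr      = clip(stats::rnorm(n, 137, 23), 60, 210)
  )

  x <- as.matrix(tab[covariate_names()])
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[scale == 0] <- 1  # constant column carries no signal
  z <- sweep(sweep(x, 2, center), 2, scale, "/")
  eta <- drop(z %*% spec$coefficients)
  if (spec$noise_sd > 0) eta <- eta + stats::rnorm(n, 0, spec$noise_sd)

  intercept <- tryCatch(
    stats::uniroot(
      function(c0) mean(stats::plogis(c0 + eta)) - spec$prevalence,
      interval = c(-30, 30), tol = 1e-10
    )$root,
    error = function(e) stop("cannot solve the intercept for the requested prevalence: ",
                             conditionMessage(e), call. = FALSE)
  )
  prob <- stats::plogis(intercept + eta)
  tab$outcome <- stats::rbinom(n, 1, prob)

  attr(tab, "oracle") <- list(
    intercept = intercept,
    coefficients = spec$coefficients,
    center = center,
    scale = scale
  )
  attr(tab, "cohort_spec") <- spec
  tab
}

#' True generative probability for cohort rows
#'
#' Recomputes `plogis(intercept + sum(beta_k z_k))` for any subset of rows,
#' using the standardization constants frozen at generation time. This is the
#' covariate-conditional event probability, i.e. the Bayes-optimal score.
#'
#' @param cohort A table produced by [generate_cohort()] (the `oracle`
#'   attribute is required), or any table plus an explicit `oracle` list.
#' @param newdata Rows to score; defaults to the whole cohort.
#' @param oracle Generative parameters; defaults to `attr(cohort, "oracle")`.
#' @return Numeric vector of probabilities.
#' @export
oracle_scores <- function(cohort, newdata = cohort, oracle = attr(cohort, "oracle")) {
  if (is.null(oracle)) {
    stop("no `oracle` attribute: the table was not made by generate_cohort()",
         call. = FALSE)
  }
  x <- as.matrix(newdata[covariate_names()])
  z <- sweep(sweep(x, 2, oracle$center), 2, oracle$scale, "/")
  stats::plogis(oracle$intercept + drop(z %*% oracle$coefficients))
}

#' Write / read a cohort CSV
#'
#' The CSV column contract (eight covariates + `outcome`, 0/1) matches what a
#' user would export from the MLDataR heart-disease table after recoding the
#' outcome to 0/1; [read_cohort()] accepts any CSV honouring it.
#'
#' @param cohort Cohort data frame.
#' @param path File path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @param outcome Name of the 0/1 outcome column in the file.
#' @export
read_cohort <- function(path, outcome = "outcome") {
  tab <- utils::read.csv(path)
  missing_cols <- setdiff(c(covariate_names(), outcome), names(tab))
  if (length(missing_cols) > 0) {
    stop("cohort CSV is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!all(tab[[outcome]] %in% c(0, 1))) {
    stop("outcome column must be 0/1", call. = FALSE)
  }
  if (outcome != "outcome") {
    tab$outcome <- tab[[outcome]]
    tab[[outcome]] <- NULL
  }
  tab
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
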