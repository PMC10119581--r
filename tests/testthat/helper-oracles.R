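# Independent oracles used to cross-check the package implementations.
# These deliberately take different computational routes than the package.

# O(n*m) pairwise win/tie/loss enumeration of the AUROC
brute_force_auroc <- function(pos, neg) {
  cmp <- outer(pos, neg, function(x, y) (x > y) + 0.5 * (x == y))
  mean(cmp)
}

# Anderson-Darling functional by exact piecewise integration:
#   A^2 = n * integral_0^1 (Fn(t) - t)^2 / (t (1 - t)) dt
# where t = Phi((x - mean) / sd) and Fn is the empirical CDF (a step
# function), so the integral is a sum of closed-form segment integrals.
ad_integral_oracle <- function(values) {
  n <- length(values)
  z <- sort((values - mean(values)) / sd(values))
  t <- pnorm(z)
  knots <- c(0, t, 1)
  # antiderivative of (c - t)^2 * (1/t + 1/(1-t)); log terms vanish when
  # their coefficient is zero (c = 0 at t = 0, c = 1 at t = 1)
  G <- function(c, t) {
    term1 <- if (c == 0) 0 else c^2 * log(t)
    term2 <- if (c == 1) 0 else (c - 1)^2 * log(1 - t)
    term1 - 2 * c * t + t^2 / 2 - (term2 + 2 * (c - 1) * (1 - t) + (1 - t)^2 / 2)
  }
  total <- 0
  for (i in 0:n) {
    c <- i / n
    lo <- knots[i + 1]
    hi <- knots[i + 2]
    if (hi > lo) total <- total + (G(c, hi) - G(c, lo))
  }
  n * total
}

# small cohort used across tests where the exact signal does not matter
tiny_cohort <- function(n = 120, seed = 11) {
  generate_cohort(cohort_spec(n_rows = n, seed = seed))
}

# adapter with a fixed scoring rule and no randomness: score = cholesterol
# rescaled to [0, 1]; deterministic across replicates
fixed_rule_adapter <- function() {
  model_adapter(
    name = "fixed_rule",
    fit = function(data) NULL,
    predict_scores = function(fit, newdata) {
      (newdata$cholesterol - 85) / (600 - 85)
    }
  )
}

# adapter that returns the true outcome as the score (perfect knowledge)
perfect_adapter <- function() {
  model_adapter(
    name = "perfect",
    fit = function(data) NULL,
    predict_scores = function(fit, newdata) as.numeric(newdata$outcome)
  )
}
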