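---
title: "Analytic sampling distributions for classifier metrics: model, defaults, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analytic sampling distributions for classifier metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(addmetrics)
```

## The two routes to a metric's sampling distribution

A binary classifier evaluated on a held-out test set yields eight metrics:
accuracy, F1, sensitivity, specificity, PPV, NPV, balanced accuracy, and the
AUROC. `addmetrics` characterises the sampling distribution of each metric
(and of XGBoost's per-feature gain shares) in two independent ways and lets
you compare them.

**Route 1 — Monte-Carlo re-splitting.** `run_replicates()` repeatedly
re-partitions the cohort into disjoint train and test sets (70:30 by
default), refits a model adapter on each train set, and archives the metric
panel computed on the corresponding test set. This is Monte-Carlo
cross-validation: the replicate-to-replicate spread mixes two sources of
variation, the composition of the test sample and the instability of the
refitted model. The empirical nine-statistic summary (min, 5th/25th/50th/
75th/95th percentiles, max, mean, SD) comes from `empirical_summary()`.

**Route 2 — the analytically derived distribution (ADD).** Each metric is
assigned a Gaussian: mean = the point estimate, variance = a closed-form
expression. For a proportion-like metric with value $p$ evaluated on $n$
test subjects,
$$\sigma^2 = \frac{p(1-p)}{n},$$
which is exact for accuracy when the $n$ correctness indicators are i.i.d.
For the AUROC, writing it as $U/(n_{pos} n_{neg})$ with $U$ the Mann–Whitney
statistic (½ per tied pair), the null-distribution variance in its
equal-group form gives
$$\sigma^2_{AUROC} = \frac{2n+1}{12 n^2} \xrightarrow{\;n\to\infty\;} \frac{1}{6n},$$
and for AUROC values between roughly 0.7 and 0.9 the proportion formula is a
serviceable approximation of the same order (at $p = 0.79$ the two SDs agree
within 25% for $n$ in the hundreds). `add_spec()` selects the formula;
`gaussian_quantile_summary()` turns the Gaussian into the same
nine-statistic row, using closed-form quantiles $\mu + z_q\sigma$.

Two conventions in the analytic tables deserve explicit statement:

- **Extremes.** A Gaussian has unbounded support, so "minimum" and
  "maximum" are not analytic objects. When a companion resampling run is
  available, `build_add_table()` clamps the extremes to its empirical
  min/max (the convention of the published tables this layout follows); in
  pure-analytic mode they are the quantiles at $10^{-4}$ and $1-10^{-4}$.
- **Which $n$.** The variance formulas need a sample size. The default is
  the test-set size ($\lfloor 0.30 N \rceil$, 275 for a 918-row cohort),
  because the metrics are computed on test subjects only; it is an explicit
  argument (`n_for_variance`) everywhere, since reasonable analysts could
  instead use the full cohort size and obtain SDs smaller by $\sqrt{0.3}$.

Applying $p(1-p)/n$ to balanced accuracy and to gain shares is an
extrapolation: neither is a proportion of $n$ independent test subjects.
Rows are produced for them anyway because the comparison itself is
informative — see "Where the Gaussian shortcut breaks" below.

## Deciding when mean and SD are enough

A Gaussian is fully described by mean and SD, so the shortcut is justified
exactly when the resampled distribution is normal-compatible.
`ad_statistic()` implements the Anderson–Darling test in its composite form
(both parameters estimated from the sample), with the small-sample
correction $A^{*2} = A^2(1 + 0.75/n + 2.25/n^2)$ and the standard piecewise
exponential p-value approximation (capped to $[10^{-7}, 1]$; the published
piecewise coefficients leave steps of a few $10^{-3}$ at their seams, which
we reproduce rather than smooth). `sufficiency_report()` runs the test on
every archived metric and gain covariate and flags `normal_compatible` at
p > 0.05. Ties in the sorted standardized sample are kept as-is (stable
sort, no jitter): the test sees the data the archive actually contains.

## The synthetic cohort: what it emulates and what it does not

`generate_cohort()` produces a heart-disease-like table: age, sex, resting
blood pressure, cholesterol, fasting blood sugar, resting ECG (ordinal
0/1/2), exertional angina, maximum heart rate, and a clinician-diagnosis
outcome. Marginals are clinically plausible (age ~ N(54, 9) years clipped to
[25, 80]; blood pressure N(132, 18) mmHg in [80, 210]; cholesterol
N(246, 52) mg/dL in [85, 600]; max HR N(137, 23) bpm in [60, 210]; sex/
angina/fasting-sugar Bernoulli 0.7/0.4/0.23; ECG categories 0.6/0.3/0.1).
The outcome is Bernoulli with logit equal to an intercept plus standardized
covariates times the preset log-odds (angina 1.1, cholesterol 1.0, max HR
−0.9, age 0.5, sex 0.35, resting BP 0.3, fasting sugar 0.25, ECG 0.2); the
intercept is solved numerically so expected prevalence matches the 0.55
target. The preset was chosen once so that the oracle (true-probability)
scorer attains AUROC ≈ 0.85 on large samples — the operating point of
published heart-disease models on cohorts of this size — and is not tuned
thereafter.

Deliberate simplifications: covariates are drawn independently (no
correlation structure between, say, age and blood pressure), there is no
missing data, and the outcome model is exactly logistic. Tests that pass on
this cohort therefore demonstrate the *mechanics* of the two routes and
their agreement under a known signal; they do not show that any particular
real cohort's metrics are normal-compatible — that is what
`sufficiency_report()` is for on real data, loaded via `read_cohort()`.

## Where the Gaussian shortcut breaks: two known effects

The oracle adapter (fixed scorer, no refitting) isolates pure re-splitting
variability, and makes two genuine properties of Monte-Carlo
cross-validation visible.

**Finite-population shrinkage.** With a fixed scorer, each subject's
correctness is a fixed 0/1 attribute, and a test set of $n$ of $N$ cohort
rows is a sample *without replacement*. The re-split SD of accuracy is
therefore
$$\sqrt{\frac{N-n}{N-1}}\;\sqrt{\frac{p(1-p)}{n}},$$
about 16% below the binomial value at a 70:30 split — the engine reproduces
the factor $\sqrt{643/917} = 0.837$ to within Monte-Carlo noise, and its
with-replacement mode (`mode = "resample"`), whose test draws are i.i.d.,
restores the ratio to 1. With refitting, model instability adds variance
with the opposite sign of this correction, which is why resampled and
analytic SDs can land close together in practice even though neither effect
is in the formula.

**Lattice ties and the AD test.** Accuracy on a fixed test size $n$ takes
values only on the lattice $k/n$. At a few thousand replicates the
Anderson–Darling test has ample power against that discreteness — tied
order statistics drag the statistic up even when the envelope is perfectly
Gaussian — so it rejects essentially always, for the engine's output and
for plain binomial draws alike. A non-rejection reported on tens of
thousands of replicates of a lattice-valued metric should be read with
suspicion; near-continuous metrics such as the AUROC (support
$\{k/(n_{pos}n_{neg})\}$ with varying class splits) are far less affected.
The practical reading: the Gaussian envelope approximates the re-split
distribution well (the quantile comparisons show it), but a literal
goodness-of-fit test on heavily tied metric values answers a different
question.

## Numerical choices

- Splits: `|train| = round(0.7 N)`; a draw leaving either class absent from
  train or test is rejected and redrawn from a fresh substream (counted).
  Stratified splitting (class proportions within one subject) by flag;
  default is plain, matching the simplest reading of "permuting the
  train-test sets".
- Seeding: per-replicate seeds are a deterministic counter function of the
  master seed, replicate index and redraw attempt, so runs are
  bit-reproducible and replicates order-insensitive; model-fitting draws use
  a substream disjoint from the split substreams.
- Undefined metrics (zero denominators, e.g. PPV with no positive calls)
  propagate as `NA`, never 0; summaries drop them with a logged count, the
  sufficiency report skips the column with a note.
- Ties in the AUROC: midranks, i.e. ½ per tied pair, so exchangeable scores
  give AUROC ½ exactly.
- Rounding: tables at 3 decimals, half-away-from-zero; all internal
  computation at full precision.
- Gain vectors are normalized to unit sum per replicate; adapters without a
  gain notion report none (nothing is imputed).
- Degenerate ADDs (point estimate 0 or 1 under the proportion formula) have
  SD 0, are flagged, and collapse all quantiles to the mean.

## Problem sizes used in the shipped checks

The packaged tests exercise the engine at 2,000 replicates on the 918-row
preset for the closed-loop properties (the reference workflow's 10,000
replicates add nothing but resolution to those checks), 1,000 samples for
the AD calibration and power studies, and 1,000 random score samples of
sizes 5–200 for the exhaustive AUROC-versus-enumeration comparison.
`scripts/acceptance.R` recomputes all headline quantities from scratch at
those sizes from a single `--seed`.

## Aggregate model ranking

`best_model_rank()` orders models by the mean of their per-metric ranks
(rank 1 = best mean on that metric). No standard definition of "best across
several metrics" exists; mean rank is this package's own screening choice,
transparent and scale-free, and should not be over-interpreted — inspect the
full tables before crowning anything.

## Known limitations

- The Mann–Whitney variance is used in its equal-group-size null form
  $(2n+1)/12n^2$; the general unequal-group null variance
  $nm(n+m+1)/12$ and value-dependent (non-null) AUROC variances such as
  Hanley–McNeil are deliberately out of scope of the analytic layer.
- The proportion formula ignores the finite-population correction discussed
  above and any refit variability: it describes an idealised i.i.d. test
  draw at a fixed model.
- Gain shares violate the proportion model's assumptions outright; their
  analytic SDs ran above the resampled ones for most covariates in every
  configuration we measured, and the matching published tables show the
  same direction.
- The synthetic generator does not emulate covariate correlation or
  missingness; conclusions about real cohorts require running the pipeline
  on the real table.
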