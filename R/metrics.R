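#' Tabulate a 2x2 confusion matrix
#'
#' Cross-tabulates binary truth against binary predictions. Label 1 is the
#' event (disease present); label 0 the non-event.
#'
#' @param truth Integer/numeric vector of true labels, values in \{0, 1\}.
#' @param pred Integer/numeric vector of predicted labels, same length.
#' @return An object of class `confusion_counts`: a list with integer fields
#'   `tp`, `fp`, `tn`, `fn` summing to `length(truth)`.
#' @examples
#' confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 1))
#' @export
confusion_counts <- function(truth, pred) {
  if (length(truth) != length(pred)) {
    stop("`truth` and `pred` must have the same length", call. = FALSE)
  }
  if (length(truth) < 1L) stop("need at least one observation", call. = FALSE)
  if (!all(truth %in% c(0, 1)) || !all(pred %in% c(0, 1))) {
    stop("labels must be 0 or 1", call. = FALSE)
  }
  out <- list(
    tp = sum(truth == 1 & pred == 1),
    fp = sum(truth == 0 & pred == 1),
    tn = sum(truth == 0 & pred == 0),
    fn = sum(truth == 1 & pred == 0)
  )
  structure(lapply(out, as.integer), class = "confusion_counts")
}

#' Confusion-matrix metrics from counts
#'
#' Computes accuracy, F1, sensitivity, specificity, PPV, NPV and balanced
#' accuracy from a 2x2 table. A metric whose denominator is zero is reported
#' as `NA` (undefined), never coerced to 0, with a warning; downstream
#' summaries skip missing values and report how many were skipped.
#'
#' @param counts A `confusion_counts` object.
#' @return A `metric_panel`: named list of metrics in \[0, 1\] (or `NA`),
#'   with `auroc = NA` (ranking information is not recoverable from counts;
#'   see [metric_panel()]) and `n_test` the total count.
#' @export
panel_from_counts <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  n <- tp + fp + tn + fn

  safe_ratio <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined (zero denominator); reported as NA", what),
              call. = FALSE)
      return(NA_real_)
    }
    num / den
  }
  sens <- safe_ratio(tp, tp + fn, "sensitivity")
  spec <- safe_ratio(tn, tn + fp, "specificity")
  ppv  <- safe_ratio(tp, tp + fp, "ppv")
  npv  <- safe_ratio(tn, tn + fn, "npv")
  f1 <- if (isTRUE(!is.na(ppv) && !is.na(sens) && (ppv + sens) > 0)) {
    2 * ppv * sens / (ppv + sens)
  } else NA_real_
  structure(list(
    accuracy = (tp + tn) / n,
    f1 = f1,
    sensitivity = sens,
    specificity = spec,
    ppv = ppv,
    npv = npv,
    balanced_accuracy = (sens + spec) / 2,
    auroc = NA_real_,
    n_test = as.integer(n)
  ), class = "metric_panel")
}

#' Mann-Whitney U statistic and rank-based AUROC
#'
#' U is the sum over all (positive, negative) score pairs of a win/tie/loss
#' indicator: 1 if the positive scores higher, 1/2 on a tie, 0 otherwise.
#' AUROC = U / (n_pos * n_neg), the probability that a random event subject
#' outscores a random non-event subject. Computed in O((n+m) log(n+m)) via
#' midranks; identical to the brute-force pairwise count.
#'
#' @param pos_scores Numeric scores of outcome-positive subjects.
#' @param neg_scores Numeric scores of outcome-negative subjects.
#' @return A `mann_whitney` object: list with `u`, `n_pos`, `n_neg`, `auroc`.
#' @examples
#' mann_whitney_u(c(0.9, 0.4), c(0.6, 0.2))  # u = 3, auroc = 0.75
#' @export
mann_whitney_u <- function(pos_scores, neg_scores) {
  if (length(pos_scores) == 0L || length(neg_scores) == 0L) {
    stop("both score groups must be non-empty", call. = FALSE)
  }
  if (!all(is.finite(pos_scores)) || !all(is.finite(neg_scores))) {
    stop("scores must be finite", call. = FALSE)
  }
  n_pos <- length(pos_scores)
  n_neg <- length(neg_scores)
  r <- rank(c(pos_scores, neg_scores))        # midranks give the 1/2-per-tie convention
  u <- sum(r[seq_len(n_pos)]) - n_pos * (n_pos + 1) / 2
  structure(
    list(u = u, n_pos = n_pos, n_neg = n_neg, auroc = u / (n_pos * n_neg)),
    class = "mann_whitney"
  )
}

#' Dichotomise scores at a cutoff
#'
#' @param scores Numeric vector of predicted scores/probabilities.
#' @param cutoff Classification threshold; label 1 iff `score >= cutoff`
#'   (inclusive at the boundary). Default 0.5.
#' @return Integer vector of 0/1 labels.
#' @export
threshold_scores <- function(scores, cutoff = 0.5) {
  if (!all(is.finite(scores))) stop("scores must be finite", call. = FALSE)
  as.integer(scores >= cutoff)
}

#' Full metric panel from scores
#'
#' Thresholds scores, tabulates the confusion matrix, and adds the rank-based
#' AUROC. This is the per-replicate panel archived by the resampling engine.
#'
#' @param truth 0/1 vector of true outcomes.
#' @param scores Numeric predicted scores (typically probabilities).
#' @param cutoff Threshold for the confusion-matrix metrics (default 0.5).
#' @return A `metric_panel` with all eight metrics and `n_test`.
#' @export
metric_panel <- function(truth, scores, cutoff = 0.5) {
  if (length(truth) != length(scores)) {
    stop("`truth` and `scores` must have the same length", call. = FALSE)
  }
  panel <- panel_from_counts(confusion_counts(truth, threshold_scores(scores, cutoff)))
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  if (length(pos) > 0L && length(neg) > 0L) {
    panel$auroc <- mann_whitney_u(pos, neg)$auroc
  } else {
    warning("AUROC undefined: one outcome class absent from the test set",
            call. = FALSE)
  }
  panel
}

#' @export
print.metric_panel <- function(x, digits = 3, ...) {
  vals <- unlist(x[metric_names()])
  cat("Metric panel (n_test =", x$n_test, ")\n")
  print(round(vals, digits))
  invisible(x)
}

# canonical metric order used in archives and tables
metric_names <- function() {
  c("accuracy", "f1", "sensitivity", "specificity", "ppv", "npv",
    "balanced_accuracy", "auroc")
}
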