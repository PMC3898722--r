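## Per-miR diagnostic threshold analysis.
##
## Each miR's continuous relative expression is evaluated as a predictor of
## hypermethylator status: a sample is predicted positive when expression
## <= threshold (the direction is fixed a priori — low expression predicts
## the phenotype — and the reverse direction is not searched). The
## threshold is chosen to maximize correct assignments CA = (TP+TN)/N on
## unrounded fractions, among candidate cutpoints placed at midpoints
## between consecutive distinct observed values plus one below the minimum
## and one above the maximum. Ties in CA are broken toward the highest
## sensitivity, then the largest threshold.

#' Build a 2x2 confusion table from binary calls
#'
#' @param predicted_positive named logical vector: predicted hypermethylator.
#' @param truth named logical vector: true hypermethylator status, same
#'   sample set.
#' @return a `confusion_table` list: `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_from_calls <- function(predicted_positive, truth) {
  if (length(predicted_positive) != length(truth))
    validation_error("prediction and truth differ in length")
  if (!is.null(names(predicted_positive)) && !is.null(names(truth))) {
    if (!setequal(names(predicted_positive), names(truth)))
      validation_error("prediction and truth cover different samples")
    truth <- truth[names(predicted_positive)]
  }
  if (anyNA(predicted_positive) || anyNA(truth))
    validation_error("missing values in prediction or truth")
  confusion_table(tp = sum(predicted_positive & truth),
                  fp = sum(predicted_positive & !truth),
                  tn = sum(!predicted_positive & !truth),
                  fn = sum(!predicted_positive & truth))
}

#' @rdname confusion_from_calls
#' @param tp,fp,tn,fn non-negative integer cell counts.
#' @export
confusion_table <- function(tp, fp, tn, fn) {
  cells <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(cells < 0) || any(cells != floor(cells)))
    validation_error("confusion cells must be non-negative integers")
  structure(lapply(as.list(cells), as.integer), class = "confusion_table")
}

safe_frac <- function(num, den) if (den == 0) NA_real_ else num / den

#' Diagnostic metrics from a confusion table
#'
#' Sensitivity, specificity, positive and negative predictive value and
#' correct assignments, as integer percentages (half-up rounding by
#' default) with the unrounded fractions retained. A metric whose
#' denominator is zero is `NA`; the others remain defined.
#'
#' @param c a `confusion_table`.
#' @param rounding `"half_up"` (default) or `"banker"`.
#' @return a `diagnostic_metrics` list: integer-percent `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `ca` plus a `fractions` sub-list of the
#'   raw values.
#' @export
metrics_from_confusion <- function(c, rounding = "half_up") {
  fr <- list(
    sensitivity = safe_frac(c$tp, c$tp + c$fn),
    specificity = safe_frac(c$tn, c$tn + c$fp),
    ppv = safe_frac(c$tp, c$tp + c$fp),
    npv = safe_frac(c$tn, c$tn + c$fn),
    ca = safe_frac(c$tp + c$tn, c$tp + c$tn + c$fp + c$fn))
  pct <- lapply(fr, function(x)
    if (is.na(x)) NA_integer_ else as.integer(apply_rounding(100 * x, rounding)))
  structure(c(pct, list(fractions = fr)), class = "diagnostic_metrics")
}

## Candidate cutpoints: midpoints between consecutive distinct sorted
## values, plus one strictly below the minimum and one strictly above the
## maximum (the two constant classifiers).
candidate_thresholds <- function(x) {
  u <- sort(unique(x))
  mids <- if (length(u) > 1) (u[-length(u)] + u[-1]) / 2 else numeric(0)
  c(u[1] - 1, mids, u[length(u)] + 1)
}

#' CA-optimal diagnostic threshold for one miR
#'
#' @param expression numeric vector of relative expression, one value per
#'   sample (no missing values; filter beforehand).
#' @param truth logical vector of hypermethylator status, both classes
#'   present.
#' @param rounding rounding rule for the reported integer percentages.
#' @param assay_id optional label carried into the result.
#' @return a `threshold_result` list: `assay_id`, `threshold`, `metrics`
#'   (a `diagnostic_metrics`), `confusion`, `ca_fraction` (unrounded CA of
#'   the optimum) and `tie_set_size` (number of CA-maximizing candidates).
#' @export
optimize_threshold <- function(expression, truth, rounding = "half_up",
                               assay_id = NULL) {
  if (length(expression) != length(truth))
    validation_error("expression and truth differ in length")
  if (anyNA(expression) || anyNA(truth))
    validation_error("missing values in expression or truth")
  if (length(expression) < 2)
    validation_error("need at least 2 samples")
  if (!any(truth) || all(truth))
    validation_error("both truth classes must be present")

  cand <- candidate_thresholds(expression)
  n <- length(expression)
  stats <- vapply(cand, function(t) {
    pred <- expression <= t
    tp <- sum(pred & truth); fp <- sum(pred & !truth)
    tn <- sum(!pred & !truth); fn <- sum(!pred & truth)
    c(ca = (tp + tn) / n, sens = tp / (tp + fn))
  }, c(ca = 0, sens = 0))

  best_ca <- max(stats["ca", ])
  tie <- which(stats["ca", ] >= best_ca - 1e-12)
  tie_set_size <- length(tie)
  tie <- tie[stats["sens", tie] >= max(stats["sens", tie]) - 1e-12]
  pick <- tie[which.max(cand[tie])]

  pred <- expression <= cand[pick]
  conf <- confusion_from_calls(pred, truth)
  structure(list(assay_id = assay_id, threshold = cand[pick],
                 metrics = metrics_from_confusion(conf, rounding),
                 confusion = conf,
                 ca_fraction = best_ca,
                 tie_set_size = tie_set_size),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "%s: threshold %.4g | sens %s spec %s ppv %s npv %s CA %s%% (ties: %d)\n",
    if (is.null(x$assay_id)) "threshold" else x$assay_id, x$threshold,
    m$sensitivity, m$specificity, m$ppv, m$npv, m$ca, x$tie_set_size))
  invisible(x)
}

#' Threshold analysis over the full miR panel
#'
#' Runs [optimize_threshold()] for every panel miR on a sample subset
#' (default: the basal-like tumors, the subtype in which the hypermethylator
#' phenotype is evaluated), using the score table's hypermethylator call as
#' truth. Samples with missing expression for a given miR are dropped
#' pairwise for that miR only.
#'
#' @param matrix an `expression_matrix`.
#' @param scores a `score_table` from [score_cohort()].
#' @param mir_panel miR assay ids (default [MIR_PANEL]).
#' @param subset character vector of sample ids, or `NULL` for all
#'   basal-like tumors in `scores`.
#' @param rounding rounding rule for reported percentages.
#' @return named list of `threshold_result`, in panel order.
#' @export
evaluate_panel <- function(matrix, scores, mir_panel = MIR_PANEL,
                           subset = NULL, rounding = "half_up") {
  if (is.null(subset))
    subset <- scores$sample_id[scores$subtype == "basal_like"]
  subset <- intersect(subset, rownames(matrix$values))
  truth_all <- stats::setNames(scores$hypermethylator, scores$sample_id)
  truth <- truth_all[subset]
  if (anyNA(truth))
    validation_error("subset contains samples without a hypermethylator call")
  if (!any(truth) || all(truth))
    validation_error("subset must contain both hypermethylator classes")

  out <- lapply(mir_panel, function(assay) {
    x <- matrix$values[subset, assay]
    keep <- !is.na(x)
    optimize_threshold(x[keep], truth[keep], rounding = rounding,
                       assay_id = assay)
  })
  stats::setNames(out, mir_panel)
}
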