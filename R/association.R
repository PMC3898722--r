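## Association statistics: subtype group summaries (mean +/- SEM),
## unpaired two-tailed t-tests between hypermethylator groups, and Pearson
## correlations for score-vs-score and miR-vs-miR relationships. No
## multiple-testing correction is applied anywhere; the pairwise output
## records how many tests were run.

#' Mean and standard error of the mean
#'
#' @param x numeric vector (NAs dropped).
#' @return list with `n`, `mean`, `sem` (sd/sqrt(n); 0 when n = 1).
#' @export
group_summary <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0) validation_error("group_summary needs at least one value")
  list(n = n, mean = mean(x),
       sem = if (n == 1) 0 else stats::sd(x) / sqrt(n))
}

#' Per-subtype expression summaries
#'
#' Mean +/- SEM of relative expression per tumor subtype per assay, normals
#' excluded. Subtypes with no tumors are omitted with a warning.
#'
#' @param matrix an `expression_matrix`.
#' @param meta a `sample_meta` data.frame.
#' @param panel assay ids to summarize (default [MIR_PANEL]).
#' @return data.frame: `subtype`, `assay_id`, `n`, `mean`, `sem`.
#' @export
subtype_summaries <- function(matrix, meta, panel = MIR_PANEL) {
  tumor_subtypes <- setdiff(SUBTYPE_LEVELS, "normal")
  rows <- list()
  for (st in tumor_subtypes) {
    ids <- meta$sample_id[meta$subtype == st & meta$role == "tumor"]
    ids <- intersect(ids, rownames(matrix$values))
    if (length(ids) == 0) {
      warning(sprintf("subtype %s has no tumors; omitted", st), call. = FALSE)
      next
    }
    for (assay in panel) {
      s <- group_summary(matrix$values[ids, assay])
      rows[[length(rows) + 1L]] <-
        data.frame(subtype = st, assay_id = assay, n = s$n,
                   mean = s$mean, sem = s$sem, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Unpaired two-tailed t-test
#'
#' Classic Student (pooled-variance) statistic by default, Welch by option.
#' Computed in closed form; two-tailed p from the t distribution.
#'
#' @param group_a,group_b numeric vectors, each with at least 2 values.
#' @param variant `"student"` or `"welch"`.
#' @return a `t_test_result` list: `mean_a`, `mean_b`, `t`, `df`, `p`,
#'   `variant`. `t` is negated under group swap; `p` is unchanged.
#' @export
unpaired_t <- function(group_a, group_b, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  a <- group_a[!is.na(group_a)]; b <- group_b[!is.na(group_b)]
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2)
    validation_error("each group needs at least 2 observations")
  va <- stats::var(a); vb <- stats::var(b)
  if (variant == "student") {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  t <- if (se == 0) 0 else (mean(a) - mean(b)) / se
  structure(list(mean_a = mean(a), mean_b = mean(b), t = t, df = df,
                 p = 2 * stats::pt(-abs(t), df), variant = variant),
            class = "t_test_result")
}

#' Pearson correlation with a two-sided p-value
#'
#' Pairwise-complete observations; p from the t transform
#' `t = r * sqrt((n-2)/(1-r^2))` with n-2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length, at least 3 complete pairs,
#'   nonzero variance in both.
#' @return a `correlation_result` list: `n`, `r`, `p`.
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) validation_error("x and y differ in length")
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) validation_error("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    validation_error("zero variance: correlation undefined")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    ((n - 1) * stats::sd(x) * stats::sd(y))
  r <- max(-1, min(1, r))
  p <- if (abs(r) >= 1) {
    .Machine$double.xmin  # degenerate perfect correlation
  } else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(t), n - 2)
  }
  structure(list(n = n, r = r, p = p), class = "correlation_result")
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("unpaired t-test (%s): mean %.4g vs %.4g, t = %.4g, df = %.4g, p = %.4g\n",
              x$variant, x$mean_a, x$mean_b, x$t, x$df, x$p))
  invisible(x)
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson correlation: r = %.3g, p = %.3g (n = %d)\n",
              x$r, x$p, x$n))
  invisible(x)
}

#' Correlation between miR score and gene-expression score
#'
#' @param scores a `score_table`.
#' @param subset optional sample ids (default: all rows of `scores`).
#' @return a `correlation_result`.
#' @export
score_correlation <- function(scores, subset = NULL) {
  rows <- if (is.null(subset)) scores else
    scores[scores$sample_id %in% subset, ]
  pearson_with_p(rows$mir_score, rows$gene_score)
}

#' All pairwise miR-miR expression correlations
#'
#' Every unordered pair of panel miRs, pairwise-complete observations, with
#' the n actually used per pair. By default computed over all tumors.
#'
#' @param matrix an `expression_matrix`.
#' @param mir_panel miR assay ids (default [MIR_PANEL]).
#' @param subset sample ids (default: every matrix row).
#' @return data.frame: `assay_a`, `assay_b`, `n`, `r`, `p`, with attribute
#'   `n_tests` flagging the number of uncorrected tests performed.
#' @export
pairwise_mir_correlations <- function(matrix, mir_panel = MIR_PANEL,
                                      subset = NULL) {
  if (is.null(subset)) subset <- rownames(matrix$values)
  vals <- matrix$values[rownames(matrix$values) %in% subset, mir_panel,
                        drop = FALSE]
  pairs <- utils::combn(mir_panel, 2)
  rows <- apply(pairs, 2, function(pr) {
    cr <- pearson_with_p(vals[, pr[1]], vals[, pr[2]])
    data.frame(assay_a = pr[1], assay_b = pr[2], n = cr$n, r = cr$r,
               p = cr$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_tests") <- nrow(out)
  out
}
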