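## Median binarization and phenotype scoring.
##
## Each assay's expression values are dichotomized at the median of the
## configured population (tumors only by default): a call is "low" iff the
## value is strictly below the median ("below the median" read strictly, so
## a value equal to the median is "normal"). The gene-expression score and
## miR score count low calls over the respective 9-assay panel; the
## hypermethylator phenotype and the low miR-expression group are threshold
## rules on those counts.

#' Per-assay binarization medians
#'
#' @param matrix an `expression_matrix`.
#' @param population character vector of sample ids to compute medians over.
#' @return named numeric vector of medians (fold units), one per assay.
#'   Standard median: midpoint of the two central order statistics for even
#'   n; missing cells are excluded. An assay with no usable value in the
#'   population is an error.
#' @export
compute_medians <- function(matrix, population) {
  vals <- matrix$values[rownames(matrix$values) %in% population, ,
                        drop = FALSE]
  if (nrow(vals) == 0) validation_error("median population has no samples")
  meds <- apply(vals, 2, stats::median, na.rm = TRUE)
  bad <- names(meds)[is.na(meds)]
  if (length(bad))
    validation_error(sprintf("assay(s) with no usable value in median population: %s",
                             paste(bad, collapse = ", ")))
  meds
}

#' Binarize an expression matrix against per-assay medians
#'
#' @param matrix an `expression_matrix`.
#' @param medians named vector from [compute_medians()], covering every
#'   matrix assay.
#' @return a `binary_call_matrix`: character matrix of `"low"` / `"normal"`
#'   (NA where expression is missing) with the medians attached as an
#'   attribute.
#' @export
binarize <- function(matrix, medians) {
  assays <- colnames(matrix$values)
  missing <- setdiff(assays, names(medians))
  if (length(missing))
    validation_error(sprintf("medians missing for assay(s): %s",
                             paste(missing, collapse = ", ")))
  calls <- ifelse(sweep(matrix$values, 2, medians[assays], `<`),
                  "low", "normal")
  structure(calls, medians = medians[assays],
            class = c("binary_call_matrix", class(calls)))
}

count_low <- function(calls_row, panel) {
  calls <- calls_row[panel]
  sum(calls == "low", na.rm = TRUE)  # missing counts as normal
}

#' Gene-expression score of one tumor
#'
#' Number of methylation-sensitive panel genes called low (below the
#' median). Missing calls count as normal (conservative against calling the
#' hypermethylator phenotype).
#'
#' @param calls_row named character vector (one `binary_call_matrix` row).
#' @param gene_panel gene assay ids.
#' @return integer in `[0, length(gene_panel)]`.
#' @export
gene_expression_score <- function(calls_row, gene_panel = GENE_PANEL) {
  count_low(calls_row, gene_panel)
}

#' Hypermethylator phenotype call
#'
#' A tumor is classified as expressing aberrant DNA hypermethylation when at
#' least `cutoff` of the methylation-sensitive biomarker genes are expressed
#' at diminished (below-median) levels.
#'
#' @param gene_score integer gene-expression score.
#' @param cutoff rule threshold (default 7 of 9).
#' @return logical.
#' @export
call_hypermethylator <- function(gene_score, cutoff = 7L) {
  gene_score >= cutoff
}

#' miR score and expression group of one tumor
#'
#' The miR score counts regulatory miRs expressed below the median; tumors
#' with score >= `cutoff` fall in the low miR-expression group, all others
#' in the high group (an exact partition).
#'
#' @param calls_row named character vector (one `binary_call_matrix` row).
#' @param mir_panel miR assay ids.
#' @param cutoff low-group rule threshold (default 6 of 9).
#' @return list with integer `score` and `group` (`"low"` or `"high"`).
#' @export
mir_score_and_group <- function(calls_row, mir_panel = MIR_PANEL,
                                cutoff = 6L) {
  score <- count_low(calls_row, mir_panel)
  list(score = score, group = if (score >= cutoff) "low" else "high")
}

#' Score a cohort
#'
#' Computes binarization medians over the configured population, binarizes,
#' and derives per-tumor gene/miR scores, the hypermethylator call and the
#' miR expression group. Only tumors are scored; calibrators may contribute
#' to medians when `median_population = "all_samples"`.
#'
#' @param matrix an `expression_matrix`.
#' @param meta a `sample_meta` data.frame.
#' @param config a [run_config()].
#' @return a `score_table` data.frame: `sample_id`, `subtype`, `gene_score`,
#'   `mir_score`, `hypermethylator`, `mir_group`, plus one `call_<assay>`
#'   column per panel assay. The per-assay medians are attached as an
#'   attribute `medians`.
#' @export
score_cohort <- function(matrix, meta, config = run_config()) {
  meta <- meta[match(rownames(matrix$values), meta$sample_id), ]
  pop <- switch(config$median_population,
                tumors_only = meta$sample_id[meta$role == "tumor"],
                all_samples = meta$sample_id)
  medians <- compute_medians(matrix, pop)
  calls <- binarize(matrix, medians)

  tumors <- meta$sample_id[meta$role == "tumor"]
  rows <- lapply(tumors, function(s) {
    row <- calls[s, ]
    gs <- gene_expression_score(row, config$gene_panel)
    ms <- mir_score_and_group(row, config$mir_panel,
                              config$mir_low_group_cutoff)
    data.frame(sample_id = s,
               subtype = as.character(meta$subtype[meta$sample_id == s]),
               gene_score = gs,
               mir_score = ms$score,
               hypermethylator = call_hypermethylator(
                 gs, config$hypermethylator_gene_cutoff),
               mir_group = ms$group,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  call_cols <- as.data.frame(calls[tumors, , drop = FALSE],
                             stringsAsFactors = FALSE)
  names(call_cols) <- paste0("call_", names(call_cols))
  out <- cbind(out, call_cols)
  rownames(out) <- NULL
  attr(out, "medians") <- medians
  attr(out, "median_population") <- config$median_population
  class(out) <- c("score_table", "data.frame")
  out
}
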