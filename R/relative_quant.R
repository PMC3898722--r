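## Comparative-Ct (2^-ddCt) relative quantification.
##
## Target Ct is normalized to the class-matched reference assay of the same
## sample (dCt), then to the mean dCt of the calibrator (normal mammoplasty)
## group for that assay (ddCt); fold change = 2^-ddCt. Averaging dCt across
## calibrators equals geometric-mean aggregation on the fold scale, so the
## calibrator group has geometric mean expression exactly 1 per assay.

#' Collapse replicate Ct measurements
#'
#' @param cts numeric vector of replicate Ct values for one sample x assay;
#'   `NA` marks an undetermined well and is dropped.
#' @return list with `mean`, `sem` (sample sd / sqrt(n); 0 when n = 1) and
#'   `n` (usable replicates). All `NA` replicates give a missing-value
#'   marker (`mean = NA`, `n = 0`) rather than an error.
#' @export
collapse_replicates <- function(cts) {
  usable <- cts[!is.na(cts)]
  n <- length(usable)
  if (n == 0) return(list(mean = NA_real_, sem = NA_real_, n = 0L))
  list(mean = mean(usable),
       sem = if (n == 1) 0 else stats::sd(usable) / sqrt(n),
       n = as.integer(n))
}

#' Delta-Ct between a target and its reference assay
#'
#' @param target_ct mean Ct of the target assay.
#' @param reference_ct mean Ct of the same sample's reference assay.
#' @return `target_ct - reference_ct` (cycles); `NA` if either is missing.
#' @export
delta_ct <- function(target_ct, reference_ct) target_ct - reference_ct

#' Relative expression from a sample's dCt and the calibrator-group dCt
#'
#' @param sample_delta_ct dCt of the sample (cycles).
#' @param calibrator_delta_ct mean dCt of the calibrator samples for the
#'   same assay (cycles).
#' @return fold change `2^-(sample_delta_ct - calibrator_delta_ct)`,
#'   strictly positive (amplification efficiency fixed at 2).
#' @export
relative_expression <- function(sample_delta_ct, calibrator_delta_ct) {
  2^-(sample_delta_ct - calibrator_delta_ct)
}

## Collapse a long ct_table into one row per sample x assay.
collapse_ct_table <- function(ct) {
  key <- interaction(ct$sample_id, ct$assay_id, drop = TRUE, sep = "\r")
  means <- tapply(ct$ct, key, function(v) mean(v, na.rm = TRUE))
  ns <- tapply(ct$ct, key, function(v) sum(!is.na(v)))
  parts <- strsplit(names(means), "\r", fixed = TRUE)
  data.frame(sample_id = vapply(parts, `[`, "", 1),
             assay_id = vapply(parts, `[`, "", 2),
             mean_ct = ifelse(ns > 0, unname(means), NA_real_),
             n = as.integer(unname(ns)),
             stringsAsFactors = FALSE)
}

#' Build the relative expression matrix for a cohort
#'
#' Runs the full comparative-Ct computation: replicate collapse, per-sample
#' dCt against the class-matched reference assay (RNU66 for miRs, beta-actin
#' for genes by default), calibrator-group mean dCt per assay, and
#' `2^-ddCt` fold changes. A sample missing its reference assay yields
#' missing cells for every target of that class (with a warning naming the
#' sample); a panel assay with no calibrator measurement at all is an error.
#'
#' @param ct a `ct_table` from [read_ct_table()] or [simulate_cohort()].
#' @param meta a `sample_meta` data.frame (supplies the calibrator group).
#' @param config a [run_config()].
#' @return an `expression_matrix`: list with `values` (samples x assays
#'   numeric matrix of fold changes, panel assays only), `calibrator_delta_ct`
#'   (named per-assay audit vector, cycles), `assay_class`, and `config`.
#' @export
build_expression_matrix <- function(ct, meta, config = run_config()) {
  calibrators <- meta$sample_id[meta$role == "calibrator"]
  if (length(calibrators) == 0)
    config_error("no calibrator samples in metadata")
  missing_meta <- setdiff(unique(ct$sample_id), meta$sample_id)
  if (length(missing_meta))
    validation_error(sprintf("ct table samples absent from metadata: %s",
                             paste(missing_meta, collapse = ", ")))

  flat <- collapse_ct_table(ct)
  samples <- meta$sample_id[meta$sample_id %in% unique(flat$sample_id)]
  panels <- list(mir = config$mir_panel, gene = config$gene_panel)
  refs <- list(mir = config$mir_reference, gene = config$gene_reference)
  assays <- c(config$mir_panel, config$gene_panel)

  values <- matrix(NA_real_, length(samples), length(assays),
                   dimnames = list(samples, assays))
  cal_dct <- stats::setNames(rep(NA_real_, length(assays)), assays)

  for (class in names(panels)) {
    ref_rows <- flat[flat$assay_id == refs[[class]], , drop = FALSE]
    ref_ct <- stats::setNames(ref_rows$mean_ct, ref_rows$sample_id)
    no_ref <- samples[is.na(ref_ct[samples])]
    if (length(no_ref))
      warning(sprintf(
        "reference assay %s missing for sample(s): %s; their %s cells are missing",
        refs[[class]], paste(no_ref, collapse = ", "), class), call. = FALSE)

    for (assay in panels[[class]]) {
      rows <- flat[flat$assay_id == assay, , drop = FALSE]
      target_ct <- stats::setNames(rows$mean_ct, rows$sample_id)
      dct <- delta_ct(target_ct[samples], ref_ct[samples])
      names(dct) <- samples
      cal <- dct[names(dct) %in% calibrators]
      cal <- cal[!is.na(cal)]
      if (length(cal) == 0)
        validation_error(sprintf(
          "assay %s has no usable calibrator measurement; cannot calibrate",
          assay))
      cal_dct[assay] <- mean(cal)
      values[, assay] <- relative_expression(dct, cal_dct[assay])
    }
  }

  structure(list(values = values, calibrator_delta_ct = cal_dct,
                 assay_class = classify_assay(assays, config),
                 config = config),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d samples x %d assays (%d missing cells)\n",
              nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  cat("assays:", paste(colnames(x$values), collapse = ", "), "\n")
  invisible(x)
}
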