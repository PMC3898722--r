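#' @keywords internal
"_PACKAGE"

## Typed condition helpers. Every validation failure in the package raises a
## classed error so callers (and the test suite) can distinguish format,
## validation, configuration and I/O problems.

mirmeth_error <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "mirmeth_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

format_error     <- function(msg) mirmeth_error(msg, "mirmeth_format_error")
validation_error <- function(msg) mirmeth_error(msg, "mirmeth_validation_error")
config_error     <- function(msg) mirmeth_error(msg, "mirmeth_config_error")
io_error         <- function(msg) mirmeth_error(msg, "mirmeth_io_error")

#' Default microRNA panel
#'
#' The nine mature miRs known or predicted to post-transcriptionally regulate
#' DNMT3b, quantified against the small-RNA reference RNU66.
#' @export
MIR_PANEL <- c("miR-29a", "miR-29b", "miR-29c", "miR-148a", "miR-148b",
               "miR-26a", "miR-26b", "miR-203", "miR-222")

#' Default methylation-sensitive biomarker gene panel
#'
#' Nine genes whose concurrent silencing defines the hypermethylator
#' phenotype, quantified against beta-actin (ACTB).
#' @export
GENE_PANEL <- c("CEACAM6", "CDH1", "CST6", "ESR1", "GNA11", "MUC1",
                "MYB", "TFF3", "SCNN1A")

SUBTYPE_LEVELS <- c("luminal_A", "luminal_B", "her2_enriched",
                    "basal_like", "normal")
ROLE_LEVELS <- c("tumor", "calibrator")

#' Pipeline run configuration
#'
#' Collects every tunable of the analysis: the assay panels and their
#' reference assays, the score cutoffs of the classification rules, which
#' population medians are computed over, the rounding convention for
#' integer-percent diagnostics, and the t-test variant.
#'
#' @param mir_panel character vector of miR assay ids (default [MIR_PANEL]).
#' @param gene_panel character vector of gene assay ids (default [GENE_PANEL]).
#' @param mir_reference reference small-RNA assay id (default `"RNU66"`).
#' @param gene_reference reference gene assay id (default `"ACTB"`).
#' @param hypermethylator_gene_cutoff a tumor is called hypermethylator when
#'   its gene-expression score (number of panel genes below the median) is
#'   at least this value. Default 7.
#' @param mir_low_group_cutoff a tumor falls in the low miR-expression group
#'   when its miR score is at least this value. Default 6.
#' @param median_population `"tumors_only"` (default) or `"all_samples"`:
#'   the sample set over which per-assay binarization medians are computed.
#' @param rounding `"half_up"` (default) or `"banker"` for integer-percent
#'   diagnostic metrics.
#' @param t_test_variant `"student"` (pooled variance, default) or `"welch"`.
#' @param seed optional integer seed recorded with the run.
#' @return an object of class `mirmeth_config` (a validated list).
#' @export
run_config <- function(mir_panel = MIR_PANEL,
                       gene_panel = GENE_PANEL,
                       mir_reference = "RNU66",
                       gene_reference = "ACTB",
                       hypermethylator_gene_cutoff = 7L,
                       mir_low_group_cutoff = 6L,
                       median_population = c("tumors_only", "all_samples"),
                       rounding = c("half_up", "banker"),
                       t_test_variant = c("student", "welch"),
                       seed = NULL) {
  median_population <- match.arg(median_population)
  rounding <- match.arg(rounding)
  t_test_variant <- match.arg(t_test_variant)

  if (length(mir_panel) == 0 || length(gene_panel) == 0)
    config_error("assay panels must be non-empty")
  refs <- c(mir_reference, gene_reference)
  if (any(refs %in% c(mir_panel, gene_panel)))
    config_error("reference assays must be disjoint from the panels")
  if (anyDuplicated(c(mir_panel, gene_panel)))
    config_error("panel assay ids must be unique across both panels")
  if (hypermethylator_gene_cutoff < 0 ||
      hypermethylator_gene_cutoff > length(gene_panel))
    config_error("hypermethylator_gene_cutoff must lie in [0, gene panel size]")
  if (mir_low_group_cutoff < 0 || mir_low_group_cutoff > length(mir_panel))
    config_error("mir_low_group_cutoff must lie in [0, miR panel size]")

  structure(list(
    mir_panel = as.character(mir_panel),
    gene_panel = as.character(gene_panel),
    mir_reference = mir_reference,
    gene_reference = gene_reference,
    hypermethylator_gene_cutoff = as.integer(hypermethylator_gene_cutoff),
    mir_low_group_cutoff = as.integer(mir_low_group_cutoff),
    median_population = median_population,
    rounding = rounding,
    t_test_variant = t_test_variant,
    seed = if (!is.null(seed)) as.integer(seed)
  ), class = "mirmeth_config")
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; absent keys keep their
#' defaults.
#'
#' @param path YAML file.
#' @return a `mirmeth_config` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) io_error(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    config_error(sprintf("unknown config keys: %s", paste(bad, collapse = ", ")))
  do.call(run_config, raw)
}

#' @export
print.mirmeth_config <- function(x, ...) {
  cat("mirmeth run configuration\n")
  cat("  miR panel  (", length(x$mir_panel), "): ",
      paste(x$mir_panel, collapse = ", "), " [ref ", x$mir_reference, "]\n",
      sep = "")
  cat("  gene panel (", length(x$gene_panel), "): ",
      paste(x$gene_panel, collapse = ", "), " [ref ", x$gene_reference, "]\n",
      sep = "")
  cat("  hypermethylator: gene score >=", x$hypermethylator_gene_cutoff,
      "| low miR group: miR score >=", x$mir_low_group_cutoff, "\n")
  cat("  medians over:", x$median_population,
      "| rounding:", x$rounding,
      "| t-test:", x$t_test_variant, "\n")
  invisible(x)
}

## Assign the assay_class enum from the configured panels/references.
classify_assay <- function(assay_id, config) {
  out <- rep(NA_character_, length(assay_id))
  out[assay_id %in% config$mir_panel] <- "mir"
  out[assay_id %in% config$gene_panel] <- "gene"
  out[assay_id == config$mir_reference] <- "mir_reference"
  out[assay_id == config$gene_reference] <- "gene_reference"
  out
}

## Round-half-up at `digits` decimal places. Base round() is round-half-even
## ("banker's"); the integer-percent tables here use half-up by default.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

apply_rounding <- function(x, rounding) {
  switch(rounding,
         half_up = round_half_up(x),
         banker = round(x),
         config_error(sprintf("unknown rounding rule '%s'", rounding)))
}
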