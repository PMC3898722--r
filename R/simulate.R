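## Synthetic tumor-cohort generator.
##
## Emulates the study design: 70 tumors across four clinical subtypes plus
## 18 normal mammoplasty calibrators, with a latent hypermethylator state
## (prevalent among basal-like tumors) that jointly suppresses the nine
## methylation-sensitive genes and most regulatory miRs. miR-29c is exempt
## from the hypermethylator miR effect and is instead suppressed in all
## basal-like tumors (its loss is subtype-wide); miR-203 carries a
## luminal-A effect. Biological variation is log-normal on the fold scale;
## a shared latent factor couples miR-26a and miR-26b, making them the
## expected top co-regulated pair. True log2 fold changes are converted to
## triplicate Ct values by inverting the comparative-Ct transform with a
## fixed target-vs-reference baseline offset, so zero-noise simulations
## round-trip exactly through quantification.

#' Cohort simulation parameters
#'
#' @param n_luminal_a,n_luminal_b,n_her2,n_basal,n_normal subtype sample
#'   counts (defaults 36, 13, 5, 16, 18: the study design).
#' @param p_hyper_basal latent hypermethylator prevalence among basal-like
#'   tumors (default 9/16).
#' @param p_hyper_nonbasal prevalence among non-basal tumors (default 0.08,
#'   a softened 2/17).
#' @param gene_suppression_log2 hypermethylator effect on the 9 biomarker
#'   genes, log2 fold (default -3).
#' @param mir_suppression_log2 hypermethylator effect on regulatory miRs
#'   other than miR-29c (default -1.5).
#' @param mir29c_basal_log2 subtype-wide miR-29c effect in all basal-like
#'   tumors (default -1.5).
#' @param mir203_luminalA_log2 miR-203 effect in luminal-A tumors
#'   (default -1.5).
#' @param biological_sd_log2 per-sample per-assay biological sd on the log2
#'   scale (default 0.8).
#' @param mir26_shared_sd_log2 sd of a shared latent factor added to both
#'   miR-26a and miR-26b (default 0.6), encoding their co-regulation.
#' @param ct_replicate_sd technical replicate sd, cycles (default 0.15).
#' @param reference_ct_mean mean Ct of the reference assays (default 24).
#' @param baseline_delta_ct fixed target-minus-reference Ct offset at fold 1
#'   (default 4 cycles; arbitrary, recorded so round-trips are exact).
#' @param n_replicates wells per sample x assay (default 3, triplicate).
#' @param seed integer seed; the cohort is fully reproducible from it.
#' @return a validated `cohort_sim_params` list.
#' @export
cohort_sim_params <- function(n_luminal_a = 36L, n_luminal_b = 13L,
                              n_her2 = 5L, n_basal = 16L, n_normal = 18L,
                              p_hyper_basal = 9 / 16,
                              p_hyper_nonbasal = 0.08,
                              gene_suppression_log2 = -3,
                              mir_suppression_log2 = -1.5,
                              mir29c_basal_log2 = -1.5,
                              mir203_luminalA_log2 = -1.5,
                              biological_sd_log2 = 0.8,
                              mir26_shared_sd_log2 = 0.6,
                              ct_replicate_sd = 0.15,
                              reference_ct_mean = 24,
                              baseline_delta_ct = 4,
                              n_replicates = 3L,
                              seed = 1L) {
  ns <- c(n_luminal_a, n_luminal_b, n_her2, n_basal, n_normal)
  if (any(ns < 0)) config_error("subtype counts must be non-negative")
  if (n_normal < 1) config_error("need at least one normal calibrator")
  if (p_hyper_basal < 0 || p_hyper_basal > 1 ||
      p_hyper_nonbasal < 0 || p_hyper_nonbasal > 1)
    config_error("prevalences must lie in [0, 1]")
  if (biological_sd_log2 < 0 || ct_replicate_sd < 0 ||
      mir26_shared_sd_log2 < 0)
    config_error("standard deviations must be non-negative")
  if (n_replicates < 1) config_error("n_replicates must be >= 1")
  structure(list(
    n_luminal_a = as.integer(n_luminal_a), n_luminal_b = as.integer(n_luminal_b),
    n_her2 = as.integer(n_her2), n_basal = as.integer(n_basal),
    n_normal = as.integer(n_normal),
    p_hyper_basal = p_hyper_basal, p_hyper_nonbasal = p_hyper_nonbasal,
    gene_suppression_log2 = gene_suppression_log2,
    mir_suppression_log2 = mir_suppression_log2,
    mir29c_basal_log2 = mir29c_basal_log2,
    mir203_luminalA_log2 = mir203_luminalA_log2,
    biological_sd_log2 = biological_sd_log2,
    mir26_shared_sd_log2 = mir26_shared_sd_log2,
    ct_replicate_sd = ct_replicate_sd,
    reference_ct_mean = reference_ct_mean,
    baseline_delta_ct = baseline_delta_ct,
    n_replicates = as.integer(n_replicates),
    seed = as.integer(seed)), class = "cohort_sim_params")
}

#' Invert the comparative-Ct transform for one sample x assay
#'
#' Generates target and reference Ct replicates such that quantification
#' against a calibrator with fold 1 recovers `true_fold` up to replicate
#' noise: target Ct ~ Normal(reference_ct + baseline_delta_ct -
#' log2(true_fold), replicate_sd).
#'
#' @param true_fold strictly positive fold change.
#' @param reference_ct mean reference-assay Ct (cycles).
#' @param replicate_sd technical sd, cycles.
#' @param n_replicates number of wells.
#' @param baseline_delta_ct target-minus-reference offset at fold 1.
#' @return list with numeric vectors `target` and `reference`.
#' @export
expression_to_ct <- function(true_fold, reference_ct, replicate_sd = 0.15,
                             n_replicates = 3L, baseline_delta_ct = 4) {
  if (!is.finite(true_fold) || true_fold <= 0)
    validation_error("true_fold must be strictly positive")
  list(target = stats::rnorm(n_replicates,
                             reference_ct + baseline_delta_ct - log2(true_fold),
                             replicate_sd),
       reference = stats::rnorm(n_replicates, reference_ct, replicate_sd))
}

#' Simulate a breast-tumor qPCR cohort with latent ground truth
#'
#' @param params a [cohort_sim_params()].
#' @param config a [run_config()] supplying panel and reference assay ids.
#' @return list with `ct` (a `ct_table`), `meta` (a `sample_meta`), and
#'   `truth`: a list holding `hypermethylator` (named logical per sample;
#'   normals are never hypermethylator) and `true_log2` (samples x panel
#'   assays matrix of true mean log2 fold changes).
#' @export
simulate_cohort <- function(params = cohort_sim_params(),
                            config = run_config()) {
  set.seed(params$seed)

  meta <- data.frame(
    sample_id = c(sprintf("LA%02d", seq_len(params$n_luminal_a)),
                  sprintf("LB%02d", seq_len(params$n_luminal_b)),
                  sprintf("H%02d", seq_len(params$n_her2)),
                  sprintf("B%02d", seq_len(params$n_basal)),
                  sprintf("N%02d", seq_len(params$n_normal))),
    subtype = rep(c("luminal_A", "luminal_B", "her2_enriched", "basal_like",
                    "normal"),
                  c(params$n_luminal_a, params$n_luminal_b, params$n_her2,
                    params$n_basal, params$n_normal)),
    role = rep(c("tumor", "calibrator"),
               c(params$n_luminal_a + params$n_luminal_b + params$n_her2 +
                   params$n_basal, params$n_normal)),
    stringsAsFactors = FALSE)
  meta$subtype <- factor(meta$subtype, levels = SUBTYPE_LEVELS)
  meta$role <- factor(meta$role, levels = ROLE_LEVELS)
  class(meta) <- c("sample_meta", "data.frame")

  n <- nrow(meta)
  is_tumor <- meta$role == "tumor"
  is_basal <- meta$subtype == "basal_like"
  p_hyper <- ifelse(!is_tumor, 0,
                    ifelse(is_basal, params$p_hyper_basal,
                           params$p_hyper_nonbasal))
  hyper <- stats::runif(n) < p_hyper

  assays <- c(config$mir_panel, config$gene_panel)
  true_log2 <- matrix(0, n, length(assays),
                      dimnames = list(meta$sample_id, assays))
  # systematic effects
  true_log2[hyper, config$gene_panel] <- params$gene_suppression_log2
  reg_mirs <- setdiff(config$mir_panel, "miR-29c")
  true_log2[hyper, reg_mirs] <- true_log2[hyper, reg_mirs] +
    params$mir_suppression_log2
  if ("miR-29c" %in% assays)
    true_log2[is_basal, "miR-29c"] <- true_log2[is_basal, "miR-29c"] +
      params$mir29c_basal_log2
  if ("miR-203" %in% assays)
    true_log2[meta$subtype == "luminal_A", "miR-203"] <-
      true_log2[meta$subtype == "luminal_A", "miR-203"] +
      params$mir203_luminalA_log2
  # biological variation: independent log-normal noise plus a shared latent
  # factor coupling miR-26a/miR-26b
  true_log2 <- true_log2 +
    matrix(stats::rnorm(n * length(assays), 0, params$biological_sd_log2),
           n, length(assays))
  shared_pair <- intersect(c("miR-26a", "miR-26b"), assays)
  if (length(shared_pair) == 2) {
    z <- stats::rnorm(n, 0, params$mir26_shared_sd_log2)
    true_log2[, shared_pair] <- true_log2[, shared_pair] + z
  }

  # reference Ct replicates: one reference assay per class, shared by all
  # targets of that class within a sample
  reps <- seq_len(params$n_replicates)
  refs <- c(config$mir_reference, config$gene_reference)
  ref_rows <- expand.grid(replicate = reps, assay_id = refs,
                          sample_id = meta$sample_id,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ref_rows$ct <- stats::rnorm(nrow(ref_rows), params$reference_ct_mean,
                              params$ct_replicate_sd)

  tgt_rows <- expand.grid(replicate = reps, assay_id = assays,
                          sample_id = meta$sample_id,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  mu <- params$reference_ct_mean + params$baseline_delta_ct -
    true_log2[cbind(tgt_rows$sample_id, tgt_rows$assay_id)]
  tgt_rows$ct <- stats::rnorm(nrow(tgt_rows), mu, params$ct_replicate_sd)

  ct <- rbind(tgt_rows, ref_rows)[, c("sample_id", "assay_id", "replicate",
                                      "ct")]
  ct$assay_class <- classify_assay(ct$assay_id, config)
  ct <- ct[order(match(ct$sample_id, meta$sample_id), ct$assay_id,
                 ct$replicate),
           c("sample_id", "assay_id", "assay_class", "replicate", "ct")]
  rownames(ct) <- NULL
  class(ct) <- c("ct_table", "data.frame")

  list(ct = ct, meta = meta,
       truth = list(hypermethylator = stats::setNames(hyper, meta$sample_id),
                    true_log2 = true_log2))
}
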