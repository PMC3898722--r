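## End-to-end orchestration and the command-line entry point.

#' Run the full analysis pipeline in memory
#'
#' Chains quantification, scoring, per-miR diagnostic threshold analysis
#' (among basal-like tumors) and association statistics.
#'
#' @param ct a `ct_table`.
#' @param meta a `sample_meta`.
#' @param config a [run_config()].
#' @return list with `matrix`, `scores`, `diagnostics`, `associations`.
#' @export
run_pipeline <- function(ct, meta, config = run_config()) {
  matrix <- build_expression_matrix(ct, meta, config)
  scores <- score_cohort(matrix, meta, config)

  basal <- scores$sample_id[scores$subtype == "basal_like"]
  diagnostics <- if (length(basal) >= 2 &&
                     length(unique(scores$hypermethylator[
                       scores$sample_id %in% basal])) == 2) {
    evaluate_panel(matrix, scores, config$mir_panel, subset = basal,
                   rounding = config$rounding)
  } else list()

  hyper_ids <- scores$sample_id[scores$hypermethylator &
                                  scores$sample_id %in% basal]
  non_ids <- setdiff(basal, hyper_ids)
  group_tests <- if (length(hyper_ids) >= 2 && length(non_ids) >= 2) {
    lapply(stats::setNames(config$mir_panel, config$mir_panel), function(a) {
      tt <- unpaired_t(matrix$values[hyper_ids, a],
                       matrix$values[non_ids, a], config$t_test_variant)
      list(assay_id = a, mean_hyper = tt$mean_a, mean_non = tt$mean_b,
           t = tt$t, df = tt$df, p = tt$p, variant = tt$variant)
    })
  } else list()

  correlations <- list(
    score = tryCatch(unclass(score_correlation(scores, subset = basal)),
                     mirmeth_error = function(e) NULL),
    pairwise = pairwise_mir_correlations(
      matrix, config$mir_panel,
      subset = meta$sample_id[meta$role == "tumor"]))

  list(matrix = matrix, scores = scores, diagnostics = diagnostics,
       associations = list(
         subtype_summaries = subtype_summaries(matrix, meta,
                                               config$mir_panel),
         group_tests = group_tests,
         correlations = correlations))
}

## ---- CLI -------------------------------------------------------------

cli_usage <- function() {
  cat("usage: mirmeth <subcommand> [options]\n",
      "subcommands:\n",
      "  simulate  --out DIR [--config FILE] [--seed N]\n",
      "  quantify  --ct FILE --meta FILE --out DIR [--config FILE]\n",
      "  score     --ct FILE --meta FILE --out DIR [--config FILE]\n",
      "  diagnose  --ct FILE --meta FILE --out DIR [--config FILE]\n",
      "  associate --ct FILE --meta FILE --out DIR [--config FILE]\n",
      "  run-all   --ct FILE --meta FILE --out DIR [--config FILE]\n",
      sep = "")
}

parse_cli_args <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--"))
      config_error(sprintf("unexpected argument '%s'", a))
    if (i == length(args))
      config_error(sprintf("option %s needs a value", a))
    opts[[substring(a, 3)]] <- args[i + 1L]
    i <- i + 2L
  }
  opts
}

cli_config <- function(opts) {
  cfg <- if (!is.null(opts$config)) read_config(opts$config) else run_config()
  if (!is.null(opts$seed)) cfg$seed <- as.integer(opts$seed)
  cfg
}

#' Command-line entry point
#'
#' Dispatches the subcommands `simulate`, `quantify`, `score`, `diagnose`,
#' `associate` and `run-all`. All accept `--config` (a YAML file mirroring
#' [run_config()] field names) and `--seed`; file-consuming subcommands take
#' `--ct` and `--meta`, and all write under `--out`.
#'
#' @param args character vector (default: the command line).
#' @return invisibly, the main result of the subcommand.
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) { cli_usage(); return(invisible(NULL)) }
  sub <- args[1]
  opts <- parse_cli_args(args[-1])
  cfg <- cli_config(opts)
  if (is.null(opts$out)) config_error("--out is required")
  out <- opts$out
  if (!dir.exists(out) &&
      !dir.create(out, recursive = TRUE, showWarnings = FALSE))
    io_error(sprintf("cannot create output directory: %s", out))

  if (sub == "simulate") {
    params <- cohort_sim_params(
      seed = if (!is.null(cfg$seed)) cfg$seed else 1L)
    sim <- simulate_cohort(params, cfg)
    write_ct_table(sim$ct, file.path(out, "ct_table.csv"))
    write_sample_metadata(sim$meta, file.path(out, "metadata.csv"))
    jsonlite::write_json(
      list(hypermethylator = as.list(sim$truth$hypermethylator),
           true_log2 = as.data.frame(sim$truth$true_log2)),
      file.path(out, "truth.json"), auto_unbox = TRUE, digits = NA)
    return(invisible(sim))
  }

  if (!sub %in% c("quantify", "score", "diagnose", "associate", "run-all")) {
    cli_usage()
    config_error(sprintf("unknown subcommand '%s'", sub))
  }
  if (is.null(opts$ct) || is.null(opts$meta))
    config_error("--ct and --meta are required")
  ct <- read_ct_table(opts$ct, cfg)
  meta <- read_sample_metadata(opts$meta)

  matrix <- build_expression_matrix(ct, meta, cfg)
  if (sub == "quantify") {
    em <- cbind(sample_id = rownames(matrix$values),
                as.data.frame(matrix$values, check.names = FALSE))
    write_tsv_full(em, file.path(out, "expression_matrix.tsv"))
    return(invisible(matrix))
  }

  scores <- score_cohort(matrix, meta, cfg)
  if (sub == "score") {
    write_tsv_full(scores, file.path(out, "scores.tsv"))
    return(invisible(scores))
  }

  res <- run_pipeline(ct, meta, cfg)
  if (sub == "diagnose") {
    jsonlite::write_json(
      lapply(res$diagnostics, unclass_threshold_result),
      file.path(out, "diagnostics.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE, na = "null")
    return(invisible(res$diagnostics))
  }
  if (sub == "associate") {
    jsonlite::write_json(
      associations_to_list(res$associations),
      file.path(out, "associations.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE, na = "null")
    return(invisible(res$associations))
  }
  write_report(res$scores, res$diagnostics, res$associations, out,
               matrix = res$matrix)
  invisible(res)
}
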