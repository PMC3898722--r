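## Reading and validation of the two tabular inputs (long-format Ct table,
## sample metadata) and serialization of all pipeline outputs.

## Auto-detect comma vs tab separation from the header line.
detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0) validation_error(sprintf("empty file: %s", path))
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) io_error(sprintf("file not found: %s", path))
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "\"", comment.char = "")
  if (nrow(df) == 0) validation_error(sprintf("no data rows in %s", path))
  df
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    format_error(sprintf("%s: missing required column(s): %s",
                         path, paste(missing, collapse = ", ")))
}

#' Read a long-format cycle-threshold table
#'
#' Expects columns `sample_id`, `assay_id`, `replicate`, `ct` in a comma- or
#' tab-separated file (dialect auto-detected from the header). Ct values are
#' non-negative reals; the literal string `"undetermined"`
#' (case-insensitive; empty cells and `NA` are accepted too) marks a
#' non-amplifying well and becomes a missing replicate. Each assay is
#' classed as panel miR, panel gene, or one of the two reference assays from
#' `config`; assays outside the configuration load with a warning.
#'
#' @param path CSV/TSV file.
#' @param config a [run_config()] object supplying panels and references.
#' @return a `ct_table`: a data.frame with columns `sample_id`, `assay_id`,
#'   `assay_class`, `replicate`, `ct` (NA = undetermined).
#' @export
read_ct_table <- function(path, config = run_config()) {
  df <- read_delim_auto(path)
  require_columns(df, c("sample_id", "assay_id", "replicate", "ct"), path)

  rep_num <- suppressWarnings(as.integer(df$replicate))
  if (anyNA(rep_num) || any(rep_num < 1))
    validation_error("replicate must be a positive integer")

  ct_chr <- trimws(df$ct)
  undet <- tolower(ct_chr) %in% c("undetermined", "na", "") | is.na(ct_chr)
  ct <- suppressWarnings(as.numeric(ct_chr))
  bad <- !undet & (is.na(ct) | ct < 0)
  if (any(bad))
    validation_error(sprintf(
      "non-numeric or negative ct value(s), e.g. '%s' (sample %s, assay %s)",
      ct_chr[bad][1], df$sample_id[bad][1], df$assay_id[bad][1]))
  ct[undet] <- NA_real_

  out <- data.frame(sample_id = df$sample_id,
                    assay_id = df$assay_id,
                    assay_class = classify_assay(df$assay_id, config),
                    replicate = rep_num,
                    ct = ct,
                    stringsAsFactors = FALSE)

  key <- paste(out$sample_id, out$assay_id, out$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    d <- out[duplicated(key), , drop = FALSE][1, ]
    validation_error(sprintf(
      "duplicate (sample, assay, replicate) key: (%s, %s, %d)",
      d$sample_id, d$assay_id, d$replicate))
  }

  unknown <- sort(unique(out$assay_id[is.na(out$assay_class)]))
  if (length(unknown))
    warning(sprintf("assay(s) outside configured panels/references: %s",
                    paste(unknown, collapse = ", ")), call. = FALSE)

  all_na <- tapply(out$ct, paste(out$sample_id, out$assay_id, sep = " / "),
                   function(v) all(is.na(v)))
  if (any(all_na))
    warning(sprintf("all replicates undetermined for: %s",
                    paste(names(all_na)[all_na], collapse = "; ")),
            call. = FALSE)

  class(out) <- c("ct_table", "data.frame")
  out
}

#' Read and validate sample metadata
#'
#' Expects columns `sample_id`, `subtype`, `role`. Subtype must be one of
#' `luminal_A`, `luminal_B`, `her2_enriched`, `basal_like`, `normal`; role
#' one of `tumor`, `calibrator`. Calibrators are exactly the normal
#' (reduction-mammoplasty) samples, and at least one is required.
#'
#' @param path CSV/TSV file.
#' @return a `sample_meta` data.frame with factor columns `subtype`, `role`.
#' @export
read_sample_metadata <- function(path) {
  df <- read_delim_auto(path)
  require_columns(df, c("sample_id", "subtype", "role"), path)
  validate_sample_metadata(
    data.frame(sample_id = trimws(df$sample_id),
               subtype = trimws(df$subtype),
               role = trimws(df$role),
               stringsAsFactors = FALSE))
}

validate_sample_metadata <- function(df) {
  if (anyDuplicated(df$sample_id))
    validation_error(sprintf("duplicate sample_id: %s",
                             df$sample_id[duplicated(df$sample_id)][1]))
  bad_sub <- setdiff(unique(df$subtype), SUBTYPE_LEVELS)
  if (length(bad_sub))
    validation_error(sprintf("unknown subtype value(s): %s",
                             paste(bad_sub, collapse = ", ")))
  bad_role <- setdiff(unique(df$role), ROLE_LEVELS)
  if (length(bad_role))
    validation_error(sprintf("unknown role value(s): %s",
                             paste(bad_role, collapse = ", ")))
  mismatch <- xor(df$role == "calibrator", df$subtype == "normal")
  if (any(mismatch))
    validation_error(sprintf(
      "role must be 'calibrator' exactly for subtype 'normal' (sample %s)",
      df$sample_id[mismatch][1]))
  if (!any(df$role == "calibrator"))
    config_error("cohort has no calibrator (normal) samples")

  df$subtype <- factor(df$subtype, levels = SUBTYPE_LEVELS)
  df$role <- factor(df$role, levels = ROLE_LEVELS)
  counts <- table(df$subtype)
  message("sample counts by subtype: ",
          paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
  class(df) <- c("sample_meta", "data.frame")
  df
}

## Write a numeric data.frame/matrix as TSV preserving full double precision
## (17 significant digits round-trips IEEE doubles through text).
format_full <- function(x) {
  if (is.double(x)) {
    out <- formatC(x, digits = 17, format = "g")
    out[is.na(x)] <- "NA"
    trimws(out)
  } else as.character(x)
}

write_tsv_full <- function(df, path) {
  out <- as.data.frame(lapply(df, format_full), check.names = FALSE,
                       stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Write a Ct table to CSV
#'
#' Missing Ct values are serialized as the literal `undetermined`, matching
#' the input convention of [read_ct_table()].
#'
#' @param ct a `ct_table` data.frame.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_ct_table <- function(ct, path) {
  out <- data.frame(sample_id = ct$sample_id, assay_id = ct$assay_id,
                    replicate = ct$replicate,
                    ct = ifelse(is.na(ct$ct), "undetermined",
                                format_full(ct$ct)),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ct_table
#' @param meta a `sample_meta` data.frame.
#' @export
write_sample_metadata <- function(meta, path) {
  out <- data.frame(sample_id = meta$sample_id,
                    subtype = as.character(meta$subtype),
                    role = as.character(meta$role), stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the full pipeline report
#'
#' Serializes the relative-expression matrix and per-tumor scores as TSV and
#' the diagnostics/association results as a structured JSON report, plus a
#' manifest listing every file with an MD5 content checksum. Reruns on
#' identical inputs produce identical checksums.
#'
#' @param scores a `score_table` from [score_cohort()].
#' @param diagnostics list of `threshold_result` from [evaluate_panel()]
#'   (may be empty).
#' @param associations list with any of `subtype_summaries`, `group_tests`,
#'   `correlations` (may be empty).
#' @param path output directory (created if needed).
#' @param matrix optional `expression_matrix` to serialize alongside.
#' @return invisibly, the manifest data.frame (file, md5).
#' @export
write_report <- function(scores, diagnostics = list(), associations = list(),
                         path, matrix = NULL) {
  if (!dir.exists(path) &&
      !dir.create(path, recursive = TRUE, showWarnings = FALSE))
    io_error(sprintf("cannot create output directory: %s", path))

  files <- character(0)

  if (!is.null(matrix)) {
    em <- as.data.frame(matrix$values, check.names = FALSE)
    em <- cbind(sample_id = rownames(matrix$values), em)
    f <- file.path(path, "expression_matrix.tsv")
    write_tsv_full(em, f)
    files <- c(files, f)
  }

  f <- file.path(path, "scores.tsv")
  write_tsv_full(scores, f)
  files <- c(files, f)

  report <- list(
    metadata = list(
      tie_rule = "expression equal to the median is called 'normal'",
      n_correlation_tests = if (!is.null(associations$correlations$pairwise))
        nrow(associations$correlations$pairwise)
    ),
    diagnostics = lapply(diagnostics, unclass_threshold_result),
    associations = associations_to_list(associations)
  )
  f <- file.path(path, "report.json")
  jsonlite::write_json(report, f, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  files <- c(files, f)

  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       pretty = TRUE)
  invisible(manifest)
}

unclass_threshold_result <- function(tr) {
  list(assay_id = tr$assay_id, threshold = tr$threshold,
       tp = tr$confusion$tp, fp = tr$confusion$fp,
       tn = tr$confusion$tn, fn = tr$confusion$fn,
       sensitivity = tr$metrics$sensitivity,
       specificity = tr$metrics$specificity,
       ppv = tr$metrics$ppv, npv = tr$metrics$npv, ca = tr$metrics$ca,
       tie_set_size = tr$tie_set_size)
}

associations_to_list <- function(a) {
  out <- list()
  if (!is.null(a$subtype_summaries)) out$subtype_summaries <- a$subtype_summaries
  if (!is.null(a$group_tests)) out$group_tests <- a$group_tests
  if (!is.null(a$correlations)) out$correlations <- a$correlations
  out
}
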