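# Fixture builders shared across test files. Everything is generated in
# code; no data files ship with the tests.

# A minimal run configuration with two-assay panels, for I/O tests.
tiny_config <- function() {
  run_config(mir_panel = c("miR-1", "miR-2"),
             gene_panel = c("GENE1", "GENE2"),
             hypermethylator_gene_cutoff = 2, mir_low_group_cutoff = 2)
}

# Long-format Ct data.frame from a named list sample -> assay -> replicate cts.
ct_df <- function(rows) {
  do.call(rbind, lapply(rows, function(r)
    data.frame(sample_id = r$s, assay_id = r$a,
               replicate = seq_along(r$ct), ct = r$ct,
               stringsAsFactors = FALSE)))
}

write_tmp <- function(df, sep = ",", ext = ".csv") {
  path <- tempfile(fileext = ext)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}

# Deterministic (noise-free) Ct table realizing the given log2 fold-change
# matrix under the comparative-Ct model: reference Ct 24, baseline offset 4.
# `log2fold` is samples x assays with assays drawn from `config` panels.
exact_ct_table <- function(log2fold, config, n_rep = 3,
                           ref_ct = 24, baseline = 4) {
  samples <- rownames(log2fold)
  assays <- colnames(log2fold)
  rows <- list()
  for (s in samples) {
    for (a in assays) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = s, assay_id = a, replicate = seq_len(n_rep),
        ct = rep(ref_ct + baseline - log2fold[s, a], n_rep),
        stringsAsFactors = FALSE)
    }
    for (r in c(config$mir_reference, config$gene_reference)) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = s, assay_id = r, replicate = seq_len(n_rep),
        ct = rep(ref_ct, n_rep), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$assay_class <- mirmeth:::classify_assay(out$assay_id, config)
  out <- out[, c("sample_id", "assay_id", "assay_class", "replicate", "ct")]
  class(out) <- c("ct_table", "data.frame")
  out
}

meta_df <- function(sample_id, subtype) {
  df <- data.frame(sample_id = sample_id, subtype = subtype,
                   role = ifelse(subtype == "normal", "calibrator", "tumor"),
                   stringsAsFactors = FALSE)
  df$subtype <- factor(df$subtype, levels = mirmeth:::SUBTYPE_LEVELS)
  df$role <- factor(df$role, levels = mirmeth:::ROLE_LEVELS)
  class(df) <- c("sample_meta", "data.frame")
  df
}

# Bare expression_matrix object around a numeric matrix, for scoring tests.
em_of <- function(values, config = run_config()) {
  structure(list(values = values,
                 calibrator_delta_ct = stats::setNames(
                   rep(4, ncol(values)), colnames(values)),
                 assay_class = mirmeth:::classify_assay(colnames(values),
                                                        config),
                 config = config),
            class = "expression_matrix")
}

# Independent brute-force oracle for the CA-optimal threshold: enumerates
# every distinct classifier of the form x <= t directly.
brute_force_ca <- function(x, truth) {
  cand <- c(min(x) - 1, sort(unique(x)))
  ca <- vapply(cand, function(t) mean((x <= t) == truth), 0)
  sens <- vapply(cand, function(t) sum(x <= t & truth) / sum(truth), 0)
  best <- max(ca)
  list(ca = best, max_sens = max(sens[ca >= best - 1e-12]))
}
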