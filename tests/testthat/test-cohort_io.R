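test_that("well-formed Ct tables load with typed records and assay classes", {
  cfg <- tiny_config()
  df <- ct_df(list(list(s = "S1", a = "miR-1", ct = c(24, 24.1, 24.2)),
                   list(s = "S1", a = "GENE1", ct = c(30, 30.1, 30.2)),
                   list(s = "S2", a = "miR-1", ct = c(25, 25.1, 25.2)),
                   list(s = "S2", a = "GENE1", ct = c(31, 31.1, 31.2))))
  # comma and tab dialects are auto-detected and equivalent
  for (sep in c(",", "\t")) {
    ct <- read_ct_table(write_tmp(df, sep = sep), cfg)
    expect_s3_class(ct, "ct_table")
    expect_equal(nrow(ct), 12L)
    expect_setequal(unique(ct$assay_class), c("mir", "gene"))
  }
})

test_that("undetermined wells become missing replicates, not errors", {
  cfg <- tiny_config()
  df <- ct_df(list(list(s = "S1", a = "miR-1", ct = c("24.0", "undetermined", "24.4")),
                   list(s = "S1", a = "miR-2", ct = rep("undetermined", 3))))
  expect_warning(ct <- read_ct_table(write_tmp(df), cfg),
                 "all replicates undetermined.*miR-2")
  expect_equal(sum(is.na(ct$ct)), 4L)
  expect_equal(collapse_replicates(ct$ct[ct$assay_id == "miR-1"])$mean, 24.2)
})

test_that("malformed Ct tables raise typed errors", {
  cfg <- tiny_config()
  ok <- ct_df(list(list(s = "S1", a = "miR-1", ct = c(24, 24, 24))))

  expect_error(read_ct_table(write_tmp(ok[, -4]), cfg),
               class = "mirmeth_format_error")
  dup <- rbind(ok, ok[1, ])
  expect_error(read_ct_table(write_tmp(dup), cfg),
               "duplicate.*S1, miR-1, 1", class = "mirmeth_validation_error")
  bad <- ok; bad$ct[1] <- "oops"
  expect_error(read_ct_table(write_tmp(bad), cfg),
               class = "mirmeth_validation_error")
  neg <- ok; neg$replicate[1] <- 0
  expect_error(read_ct_table(write_tmp(neg), cfg),
               class = "mirmeth_validation_error")
})

test_that("assays outside the configured panels load with a warning", {
  cfg <- tiny_config()
  df <- ct_df(list(list(s = "S1", a = "miR-1", ct = c(24, 24, 24)),
                   list(s = "S1", a = "miR-999", ct = c(25, 25, 25))))
  expect_warning(ct <- read_ct_table(write_tmp(df), cfg), "miR-999")
  expect_equal(nrow(ct), 6L)
  expect_true(all(is.na(ct$assay_class[ct$assay_id == "miR-999"])))
})

test_that("sample metadata validates enums, roles and calibrators", {
  full <- data.frame(
    sample_id = sprintf("S%02d", 1:88),
    subtype = rep(c("luminal_A", "luminal_B", "her2_enriched", "basal_like",
                    "normal"), c(36, 13, 5, 16, 18)),
    role = rep(c("tumor", "calibrator"), c(70, 18)),
    stringsAsFactors = FALSE)
  msg <- capture_messages(meta <- read_sample_metadata(write_tmp(full)))
  expect_match(msg, "luminal_A=36.*luminal_B=13.*her2_enriched=5.*basal_like=16.*normal=18")
  expect_equal(as.vector(table(meta$subtype)), c(36, 13, 5, 16, 18))

  bad_role <- full; bad_role$role[1] <- "calibrator"
  expect_error(read_sample_metadata(write_tmp(bad_role)),
               class = "mirmeth_validation_error")
  bad_sub <- full; bad_sub$subtype[1] <- "claudin_low"
  expect_error(read_sample_metadata(write_tmp(bad_sub)),
               "claudin_low", class = "mirmeth_validation_error")
  no_cal <- full[full$role == "tumor", ]
  expect_error(read_sample_metadata(write_tmp(no_cal)),
               class = "mirmeth_config_error")
  empty <- tempfile(fileext = ".csv")
  writeLines("sample_id,subtype,role", empty)
  expect_error(read_sample_metadata(empty),
               class = "mirmeth_validation_error")
})

test_that("Ct round-trip through disk preserves full double precision", {
  cfg <- tiny_config()
  set.seed(42)
  df <- ct_df(list(list(s = "S1", a = "miR-1", ct = rnorm(3, 24, 0.2)),
                   list(s = "S1", a = "miR-2", ct = rnorm(3, 27, 0.2))))
  df$assay_class <- mirmeth:::classify_assay(df$assay_id, cfg)
  class(df) <- c("ct_table", "data.frame")
  path <- tempfile(fileext = ".csv")
  write_ct_table(df, path)
  back <- read_ct_table(path, cfg)
  expect_identical(back$ct, df$ct)   # exact, not just near
})

test_that("write_report produces the files, a checksum manifest, and is deterministic", {
  cfg <- run_config()
  sim <- simulate_cohort(cohort_sim_params(seed = 3))
  res <- suppressMessages(run_pipeline(sim$ct, sim$meta, cfg))

  d1 <- tempfile(); d2 <- tempfile()
  m1 <- write_report(res$scores, res$diagnostics, res$associations, d1,
                     matrix = res$matrix)
  m2 <- write_report(res$scores, res$diagnostics, res$associations, d2,
                     matrix = res$matrix)
  expect_setequal(m1$file,
                  c("expression_matrix.tsv", "scores.tsv", "report.json"))
  expect_true(file.exists(file.path(d1, "manifest.json")))
  expect_identical(m1$md5, m2$md5)  # rerun on same inputs -> same checksums

  # expression matrix TSV round-trips to full stored precision
  em <- utils::read.delim(file.path(d1, "expression_matrix.tsv"),
                          check.names = FALSE)
  got <- as.matrix(em[, -1])
  want <- res$matrix$values
  rownames(got) <- em$sample_id
  expect_identical(got, want)

  # empty diagnostics: report still writes, with an empty array
  d3 <- tempfile()
  write_report(res$scores, list(), list(), d3)
  rep <- jsonlite::read_json(file.path(d3, "report.json"))
  expect_length(rep$diagnostics, 0)
})
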