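test_that("confusion tables count exactly", {
  truth <- c(rep(TRUE, 9), rep(FALSE, 7))
  perfect <- confusion_from_calls(truth, truth)
  expect_equal(perfect[c("tp", "fp", "tn", "fn")],
               list(tp = 9L, fp = 0L, tn = 7L, fn = 0L))
  all_pos <- confusion_from_calls(rep(TRUE, 16), truth)
  expect_equal(all_pos[c("tp", "fp", "tn", "fn")],
               list(tp = 9L, fp = 7L, tn = 0L, fn = 0L))
  # the reported low/normal pattern for miR-26a: all 9 hypermethylators low,
  # 4 of 7 non-hypermethylators normal
  pred <- c(rep(TRUE, 9), rep(TRUE, 3), rep(FALSE, 4))
  c26a <- confusion_from_calls(pred, truth)
  expect_equal(c26a[c("tp", "fp", "tn", "fn")],
               list(tp = 9L, fp = 3L, tn = 4L, fn = 0L))

  expect_error(confusion_from_calls(stats::setNames(c(TRUE, FALSE), c("a", "b")),
                                    stats::setNames(c(TRUE, FALSE), c("c", "d"))),
               class = "mirmeth_validation_error")
})

test_that("diagnostic metrics round half-up and NA out zero denominators", {
  m26a <- metrics_from_confusion(confusion_table(tp = 9, fp = 3, tn = 4, fn = 0))
  expect_equal(m26a[c("sensitivity", "specificity", "ppv", "npv", "ca")],
               list(sensitivity = 100L, specificity = 57L, ppv = 75L,
                    npv = 100L, ca = 81L))
  m29b <- metrics_from_confusion(confusion_table(tp = 9, fp = 4, tn = 3, fn = 0))
  expect_equal(m29b[c("sensitivity", "specificity", "ppv", "npv", "ca")],
               list(sensitivity = 100L, specificity = 43L, ppv = 69L,
                    npv = 100L, ca = 75L))
  # zero-denominator contract: only the undefined metric is NA
  none_pred <- metrics_from_confusion(confusion_table(tp = 0, fp = 0, tn = 4, fn = 2))
  expect_true(is.na(none_pred$ppv))
  expect_false(anyNA(none_pred[c("sensitivity", "specificity", "npv", "ca")]))
  # banker rounding is available by config: 62.5 rounds to 62, not 63
  m203 <- metrics_from_confusion(confusion_table(tp = 7, fp = 4, tn = 3, fn = 2),
                                 rounding = "banker")
  expect_equal(m203$ca, 62L)
})

test_that("the optimizer separates separable classes and reports ties", {
  x <- c(0.2, 0.3, 0.4, 1.1, 1.5, 2.0)
  truth <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  res <- optimize_threshold(x, truth)
  expect_equal(res$metrics$ca, 100L)
  expect_gt(res$threshold, 0.4)
  expect_lt(res$threshold, 1.1)
  expect_equal(res$tie_set_size, 1L)

  # all values identical: only the two constant classifiers exist
  res2 <- optimize_threshold(rep(1, 6), truth)
  expect_equal(res2$ca_fraction, 0.5)   # max(prevalence, 1 - prevalence)

  expect_error(optimize_threshold(x, rep(TRUE, 6)),
               class = "mirmeth_validation_error")
  expect_error(optimize_threshold(1, TRUE), class = "mirmeth_validation_error")
})

test_that("optimizer matches the brute-force oracle and honors tie-breaks", {
  set.seed(31)
  for (i in 1:300) {
    n <- sample(2:12, 1)
    k <- sample(seq_len(n - 1), 1)
    truth <- sample(c(rep(TRUE, k), rep(FALSE, n - k)))
    x <- round(runif(n, 0, 3), sample(0:2, 1))  # induce ties in the values
    res <- optimize_threshold(x, truth)
    oracle <- brute_force_ca(x, truth)
    expect_equal(res$ca_fraction, oracle$ca, tolerance = 1e-12)
    # tie-break: highest sensitivity among CA maximizers
    expect_equal(res$metrics$fractions$sensitivity, oracle$max_sens,
                 tolerance = 1e-12)
    # achieved CA is at least each constant classifier's
    expect_gte(res$ca_fraction + 1e-12, max(mean(truth), 1 - mean(truth)))
  }
})

test_that("the optimizer depends only on the ranks of the expression values", {
  set.seed(32)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    truth <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (all(truth) || !any(truth)) next
    x <- runif(n, 0.05, 5)
    a <- optimize_threshold(x, truth)
    b <- optimize_threshold(log(x), truth)       # strictly increasing map
    expect_equal(a$ca_fraction, b$ca_fraction, tolerance = 1e-12)
    expect_equal(a$confusion, b$confusion)
  }
})

test_that("Bayes consistency links PPV to sensitivity, specificity and prevalence", {
  set.seed(33)
  for (i in 1:200) {
    cells <- as.list(stats::setNames(sample(0:20, 4, replace = TRUE),
                                     c("tp", "fp", "tn", "fn")))
    c <- do.call(confusion_table, cells)
    f <- metrics_from_confusion(c)$fractions
    n <- c$tp + c$fp + c$tn + c$fn
    if (n == 0 || is.na(f$sensitivity) || is.na(f$specificity) ||
        is.na(f$ppv)) next
    pi <- (c$tp + c$fn) / n
    expect_equal(f$ppv,
                 f$sensitivity * pi /
                   (f$sensitivity * pi + (1 - f$specificity) * (1 - pi)),
                 tolerance = 1e-12)
  }
})

test_that("evaluate_panel runs per miR over the basal-like subset", {
  sim <- simulate_cohort(cohort_sim_params(seed = 6))
  em <- suppressWarnings(build_expression_matrix(sim$ct, sim$meta))
  sc <- score_cohort(em, sim$meta)
  res <- evaluate_panel(em, sc)
  expect_named(res, MIR_PANEL)
  for (r in res) {
    base <- with(r$confusion, max(tp + fn, tn + fp) / (tp + fp + tn + fn))
    expect_gte(r$ca_fraction + 1e-12, base)
  }
  # a subset with a single truth class is rejected
  hyper_ids <- sc$sample_id[sc$hypermethylator]
  expect_error(evaluate_panel(em, sc, subset = hyper_ids),
               class = "mirmeth_validation_error")
})
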