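test_that("preset dichotomizations collapse the reference tables to the expected 2x2s", {
  co <- reference_cohort()
  bt_fna <- dichotomize(tabulate_stage(co, "fna"), preset_scheme("fna"))
  expect_equal(unlist(bt_fna), c(tp = 3213L, fp = 39L, fn = 331L, tn = 224L))
  bt_fs <- dichotomize(tabulate_stage(co, "fs"), preset_scheme("fs"))
  expect_equal(unlist(bt_fs), c(tp = 3334L, fp = 0L, fn = 210L, tn = 263L))

  tab <- tabulate_stage(co, "fna")
  expect_error(dichotomize(tab, scheme(fna_levels())),
               class = "fnafs_value_error") # all-positive is degenerate
  expect_error(dichotomize(tab, scheme("MALIGNANCY")),
               class = "fnafs_value_error") # wrong vocabulary
})

test_that("metric panels match the published values at one-decimal display precision", {
  met_fna <- compute_metrics(binary_table(3213, 39, 331, 224))
  expect_equal(unname(100 * round(metric_estimates(met_fna), 3)),
               c(90.3, 90.7, 85.2, 98.8, 40.4))
  met_fs <- compute_metrics(binary_table(3334, 0, 210, 263))
  expect_equal(unname(100 * round(metric_estimates(met_fs), 3)),
               c(94.5, 94.1, 100, 100, 55.6))
  # perfect classifier
  met_perfect <- compute_metrics(binary_table(1, 0, 0, 1))
  expect_equal(unname(metric_estimates(met_perfect)), rep(1, 5))
  # zero denominator: npv undefined when nothing tests negative
  met_nd <- compute_metrics(binary_table(5, 2, 0, 0))
  expect_true(is.na(met_nd$npv$estimate))
  expect_false(is.na(met_nd$accuracy$estimate))
})

test_that("confidence intervals contain the point estimate under both methods", {
  tables <- list(binary_table(3213, 39, 331, 224),
                 binary_table(3334, 0, 210, 263),
                 binary_table(7, 3, 2, 8),
                 binary_table(1, 0, 0, 1))
  for (bt in tables) {
    for (m in c("wilson", "clopper-pearson")) {
      met <- compute_metrics(bt, ci_method = m)
      for (nm in c("accuracy", "sensitivity", "specificity", "ppv", "npv")) {
        e <- met[[nm]]
        expect_true(e$lower <= e$estimate && e$estimate <= e$upper,
                    info = paste(m, nm))
      }
    }
  }
  # the two methods disagree (they are genuinely different procedures)
  w <- compute_metrics(binary_table(7, 3, 2, 8))$sensitivity
  cp <- compute_metrics(binary_table(7, 3, 2, 8),
                        ci_method = "clopper-pearson")$sensitivity
  expect_false(isTRUE(all.equal(w$lower, cp$lower)))
})

test_that("dichotomized metrics agree with brute-force record-level counting", {
  for (seed in 1:6) {
    co <- random_cohort(n = 211, seed = seed)
    pos <- sample(fna_levels(), sample(1:5, 1))
    oc <- oracle_counts(co, "fna", pos)
    bt <- dichotomize(tabulate_stage(co, "fna"), scheme(pos))
    expect_equal(unlist(bt), oc, ignore_attr = TRUE)
    met <- compute_metrics(bt)
    if (oc[["tp"]] + oc[["fn"]] > 0) {
      expect_equal(met$sensitivity$estimate,
                   oc[["tp"]] / (oc[["tp"]] + oc[["fn"]]))
    }
    if (oc[["tn"]] + oc[["fp"]] > 0) {
      expect_equal(met$specificity$estimate,
                   oc[["tn"]] / (oc[["tn"]] + oc[["fp"]]))
    }
  }
})

test_that("outcome-label swap and positivity monotonicity behave as identities", {
  bt <- binary_table(31, 7, 11, 23)
  swapped <- binary_table(23, 11, 7, 31) # relabel events <-> non-events
  m1 <- compute_metrics(bt)
  m2 <- compute_metrics(swapped)
  expect_equal(m2$sensitivity$estimate, m1$specificity$estimate)
  expect_equal(m2$specificity$estimate, m1$sensitivity$estimate)
  expect_equal(m2$ppv$estimate, m1$npv$estimate)
  expect_equal(m2$npv$estimate, m1$ppv$estimate)

  tab <- tabulate_stage(reference_cohort(), "fna")
  grow <- list(c("VI"), c("VI", "V"), c("VI", "V", "IV"),
               c("VI", "V", "IV", "III"), c("VI", "V", "IV", "III", "II"))
  bts <- lapply(grow, function(p) dichotomize(tab, scheme(p)))
  tps <- vapply(bts, function(b) b$tp, integer(1))
  tns <- vapply(bts, function(b) b$tn, integer(1))
  expect_true(all(diff(tps) >= 0))
  expect_true(all(diff(tns) <= 0))
})

test_that("scheme search enumerates the family exhaustively and ranks correctly", {
  tab <- tabulate_stage(reference_cohort(), "fna")
  thr <- search_schemes(tab, criterion = "accuracy", family = "threshold")
  expect_equal(nrow(thr), 5L) # contiguous top-k, k = 1..5
  # brute-force recomputation of the full ranking
  brute <- vapply(1:5, function(k) {
    bt <- dichotomize(tab, scheme(fna_levels()[1:k]))
    (bt$tp + bt$tn) / (bt$tp + bt$fp + bt$fn + bt$tn)
  }, numeric(1))
  expect_equal(sort(thr$accuracy, decreasing = TRUE), sort(brute, decreasing = TRUE))
  # raw accuracy is maximized by the III..VI threshold, not the clinical
  # V+VI preset - the preset stays authoritative for reporting
  expect_equal(thr$positive[1L], "VI+V+IV+III")
  expect_gt(thr$accuracy[1L],
            thr$accuracy[thr$positive == "VI+V"])

  sub <- search_schemes(tabulate_stage(reference_cohort(), "fs"),
                        family = "subset")
  expect_equal(nrow(sub), 2^4 - 2) # counting identity

  # pre-dichotomized 2-row table: single scheme, metrics equal the direct 2x2
  tb2 <- contingency_table(matrix(c(30L, 5L, 10L, 55L), 2, byrow = TRUE),
                           row_labels = c("POS", "NEG"))
  one <- search_schemes(tb2, family = "threshold")
  expect_equal(nrow(one), 1L)
  expect_equal(one$accuracy, (30 + 55) / 100)

  expect_error(search_schemes(tab, criterion = "auc"),
               class = "fnafs_value_error")
})
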