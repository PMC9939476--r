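test_that("the FNA+sFS rule reproduces the combined reference table cell for cell", {
  co <- apply_cascade(reference_cohort(), fna_sfs_rule())
  expect_equal(nrow(co), 3807L)
  tab <- tabulate_stage(co, "combined")
  expected <- matrix(c(3448, 21, 49, 16, 45, 224, 2, 2),
                     ncol = 2, byrow = TRUE,
                     dimnames = list(fs_levels(), outcome_levels()))
  expect_equal(unclass(tab$counts), expected, ignore_attr = TRUE)
  # outcome conservation
  expect_equal(sum(tab$counts[, "MALIGNANT"]),
               sum(co$outcome == "MALIGNANT"))
})

test_that("identity and full-deferral cascades degenerate as expected", {
  co <- random_cohort(n = 140, seed = 3)
  # all TERMINAL: combined mirrors a relabeled first stage, no second tests
  ident <- cascade_rule(stats::setNames(
    c("MALIGNANCY", "MALIGNANCY", "BENIGN", "BENIGN", "BENIGN", "BENIGN"),
    fna_levels()), name = "terminal-only")
  out <- apply_cascade(co, ident)
  expect_equal(sum(out$fs_performed), 0L)
  expect_equal(as.character(out$combined_category),
               unname(ident$actions[as.character(co$fna_category)]))
  # all DEFER: combined equals FS, everyone consumes the second test
  full <- cascade_rule(stats::setNames(rep("DEFER", 6), fna_levels()),
                       name = "defer-all")
  out2 <- apply_cascade(co, full)
  expect_equal(sum(out2$fs_performed), nrow(co))
  expect_equal(as.character(out2$combined_category),
               as.character(co$fs_category))

  partial <- cascade_rule(c(VI = "MALIGNANCY"), name = "VI only")
  expect_error(apply_cascade(co, partial),
               class = "fnafs_rule_coverage_error")
})

test_that("cascade structure: terminal rows plus deferred second-stage table", {
  for (seed in 1:5) {
    co <- random_cohort(n = 260, seed = seed)
    out <- apply_cascade(co, fna_sfs_rule())
    expect_equal(nrow(out), nrow(co)) # record conservation
    combined <- tabulate_stage(out, "combined")$counts
    term <- out[!out$fs_performed, ]
    defer <- out[out$fs_performed, ]
    rebuilt <- matrix(0L, 4, 2, dimnames = list(fs_levels(), outcome_levels()))
    if (nrow(term)) {
      t1 <- table(term$combined_category, term$outcome)
      rebuilt <- rebuilt + unclass(t1)[fs_levels(), outcome_levels()]
    }
    if (nrow(defer)) {
      t2 <- table(defer$fs_category, defer$outcome)
      rebuilt <- rebuilt + unclass(t2)[fs_levels(), outcome_levels()]
    }
    expect_equal(unclass(combined), rebuilt, ignore_attr = TRUE)
  }
})

test_that("second-test usage and costs match the printed deferral accounting", {
  co <- reference_cohort()
  u <- usage_and_cost(co, fna_sfs_rule(), cost_model(fna = 170, fs = 20))
  expect_equal(u$deferred, 1220L)
  expect_equal(u$n, 3807L)
  expect_equal(round(100 * u$deferred_fraction), 32)
  # deferral is exactly 1 - (Bethesda VI count / N) under this rule
  expect_equal(u$deferred_fraction, 1 - 2587 / 3807)
  expect_equal(u$cost_cascade - u$cost_first_only, 1220 * 20)
  expect_equal(u$cost_both - u$cost_first_only, 3807 * 20)
  expect_equal(u$savings_vs_both, (3807 - 1220) * 20)

  ident <- cascade_rule(stats::setNames(
    c("MALIGNANCY", "MALIGNANCY", "BENIGN", "BENIGN", "BENIGN", "BENIGN"),
    fna_levels()))
  u0 <- usage_and_cost(co, ident)
  expect_equal(u0$deferred, 0L)
  expect_equal(u0$cost_cascade, u0$cost_first_only)

  expect_error(cost_model(fna = NA), class = "fnafs_cost_model_error")
  expect_error(cost_model(fs = -1), class = "fnafs_cost_model_error")
})

test_that("flow tables carry the printed FNA-to-FS shift counts", {
  co <- reference_cohort()
  ft <- flow_table(co, "fna", "fs")
  m <- apply(ft$counts, c(1, 2), sum)
  expect_equal(m["VI", "MALIGNANCY"], 2452)
  expect_equal(m["V", "MALIGNANCY"], 608)
  expect_equal(m["III", "MALIGNANCY"], 232)
  benind <- m[, "BENIGN"] + m[, "INDETERMINATE"]
  expect_equal(unname(benind[fna_levels()]), c(98, 38, 18, 74, 100, 43))
  expect_equal(sum(benind), 371)
  # summing flows over destinations recovers the FNA table
  expect_equal(unname(rowSums(ft$counts[, , "MALIGNANT"])),
               unname(tabulate_stage(co, "fna")$counts[, "MALIGNANT"]))

  solo <- cohort(fna_category = "VI", fs_category = "MALIGNANCY",
                 outcome = "MALIGNANT")
  fts <- flow_table(solo, "fna", "fs")
  expect_equal(sum(fts$counts), 1)

  j <- jsonlite::fromJSON(sankey_json(ft), simplifyVector = FALSE)
  expect_length(j$nodes, 10) # 6 FNA + 4 FS, fixed vocabulary order
  expect_equal(j$nodes[[1]]$name, "fna:VI")
  vals <- vapply(j$links, function(l) l$value, numeric(1))
  expect_equal(sum(vals), 3807)
  expect_true(all(vapply(j$links, function(l) l$malignant + l$benign == l$value,
                         logical(1))))
})
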