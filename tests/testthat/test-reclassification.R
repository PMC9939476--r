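test_that("marginal NRI reproduces the published comparisons as exact fraction sums", {
  fna <- binary_table(3213, 39, 331, 224)
  fs <- binary_table(3334, 0, 210, 263)
  casc <- binary_table(3448, 21, 96, 242)

  r1 <- nri_from_marginals(fna, fs)
  expect_equal(r1$nri, 121 / 3544 + 39 / 263)
  expect_equal(round(r1$nri, 3), 0.182)
  expect_equal(r1$pairing, "MARGINAL_ONLY")
  expect_null(r1$se)
  expect_null(r1$ci95)

  r2 <- nri_from_marginals(fna, casc)
  expect_equal(r2$nri, 235 / 3544 + 18 / 263)
  expect_equal(round(r2$nri, 3), 0.135)

  # identity comparison and cohort-mismatch guard
  expect_equal(nri_from_marginals(fna, fna)$nri, 0)
  expect_error(nri_from_marginals(fna, binary_table(10, 5, 3, 2)),
               class = "fnafs_cohort_mismatch_error")
})

test_that("paired NRI reproduces the published point estimates, CIs and p-values", {
  co <- reference_cohort()
  r <- nri_paired(co, "fna", preset_scheme("fna"), "fs", preset_scheme("fs"))
  expect_equal(round(r$nri, 3), 0.182)
  expect_equal(r$pairing, "PAIRED_RECORDS")
  expect_equal(round(r$ci95, 3), c(0.138, 0.227))
  expect_lt(r$p_value, 0.001)

  casc <- apply_cascade(co)
  r2 <- nri_paired(casc, "fna", preset_scheme("fna"),
                   "combined", preset_scheme("cascade"))
  expect_equal(round(r2$nri, 3), 0.135)
  expect_equal(round(r2$ci95, 3), c(0.103, 0.167))
  expect_lt(r2$p_value, 0.001)
})

test_that("a hand-enumerated 4-record cohort gives nri_events = 0.5", {
  # events: one moves up (neg -> pos), one stays; non-events: no movement
  co <- cohort(fna_category = c("II", "VI", "II", "II"),
               fs_category = c("MALIGNANCY", "MALIGNANCY", "BENIGN", "BENIGN"),
               outcome = c("MALIGNANT", "MALIGNANT", "BENIGN", "BENIGN"))
  r <- nri_paired(co, "fna", scheme(c("V", "VI")), "fs", scheme("MALIGNANCY"))
  expect_equal(r$nri_events, 0.5)
  expect_equal(r$nri_nonevents, 0)
  expect_equal(r$nri, 0.5)
  # se from the up/down proportions: events p_up=.5, p_down=0 -> .25/2
  expect_equal(r$se, sqrt((0.5 + 0 - 0.25) / 2 + 0))
})

test_that("identical schemes give NRI 0 with the p = 1 convention", {
  co <- toy_cohort()
  r <- nri_paired(co, "fna", scheme(c("V", "VI")), "fna", scheme(c("V", "VI")))
  expect_equal(r$nri, 0)
  expect_equal(r$se, 0)
  expect_equal(r$p_value, 1)
})

test_that("paired point estimate equals the marginal estimator and is antisymmetric", {
  for (seed in 1:6) {
    co <- random_cohort(n = 173, seed = seed)
    old_s <- scheme(c("V", "VI"))
    new_s <- scheme("MALIGNANCY")
    paired <- nri_paired(co, "fna", old_s, "fs", new_s)
    marg <- nri_from_marginals(
      dichotomize(tabulate_stage(co, "fna"), old_s),
      dichotomize(tabulate_stage(co, "fs"), new_s))
    expect_equal(paired$nri, marg$nri)
    expect_equal(paired$nri_events, marg$nri_events)
    expect_equal(paired$nri_nonevents, marg$nri_nonevents)
    # antisymmetry under direction reversal, both estimators
    rev_paired <- nri_paired(co, "fs", new_s, "fna", old_s)
    expect_equal(rev_paired$nri, -paired$nri)
    rev_marg <- nri_from_marginals(
      dichotomize(tabulate_stage(co, "fs"), new_s),
      dichotomize(tabulate_stage(co, "fna"), old_s))
    expect_equal(rev_marg$nri, -marg$nri)
  }
})

test_that("under a dominating new test the mean estimated NRI tracks dSens + dSpec", {
  # generating model: old test sens .80 / spec .70; new sens .92 / spec .85
  delta <- (0.92 - 0.80) + (0.85 - 0.70)
  set.seed(7)
  nris <- replicate(40, {
    n <- 600
    ev <- stats::runif(n) < 0.5
    old_pos <- ifelse(ev, stats::runif(n) < 0.80, stats::runif(n) < 0.30)
    new_pos <- ifelse(ev, stats::runif(n) < 0.92, stats::runif(n) < 0.15)
    co <- cohort(fna_category = ifelse(old_pos, "VI", "II"),
                 fs_category = ifelse(new_pos, "MALIGNANCY", "BENIGN"),
                 outcome = ifelse(ev, "MALIGNANT", "BENIGN"))
    nri_paired(co, "fna", scheme("VI"), "fs", scheme("MALIGNANCY"))$nri
  })
  mc_se <- stats::sd(nris) / sqrt(length(nris))
  expect_gt(mean(nris), 0)
  expect_lt(abs(mean(nris) - delta), 4 * mc_se)
})

test_that("reclassification results serialize to forest-plot JSON fields", {
  co <- reference_cohort()
  r <- nri_paired(co, "fna", preset_scheme("fna"), "fs", preset_scheme("fs"))
  j <- jsonlite::fromJSON(reclassification_json(r))
  expect_equal(j$estimate, r$nri)
  expect_equal(j$ci_low, r$ci95[[1]])
  expect_equal(j$ci_high, r$ci95[[2]])
  expect_equal(j$p, r$p_value)
  # marginal results omit the unidentifiable fields
  jm <- jsonlite::fromJSON(reclassification_json(
    nri_from_marginals(binary_table(3213, 39, 331, 224),
                       binary_table(3334, 0, 210, 263))))
  expect_null(jm[["ci_low"]])
  expect_null(jm[["p"]])
})
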