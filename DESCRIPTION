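Package: fnafs
Title: Diagnostic Accuracy of Single and Staged Thyroid Nodule Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for evaluating single and staged (triage) diagnostic
    classification schemes for thyroid nodules against final pathology:
    contingency tabulation of fine-needle aspiration (Bethesda) and
    intraoperative frozen-section calls, dichotomization and the five
    standard diagnostic-accuracy metrics with Wilson or Clopper-Pearson
    confidence intervals, the categorical Net Reclassification Index for
    paired binary classifiers, staged "FNA plus selective frozen section"
    cascade rules with test-usage and cost accounting, Sankey-style flow
    tables, and a seeded synthetic-cohort generator together with a
    deterministic reconstruction of a 3807-patient reference cohort from
    published summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
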