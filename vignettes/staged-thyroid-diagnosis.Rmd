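---
title: "Evaluating single and staged diagnostic schemes for thyroid nodules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating single and staged diagnostic schemes for thyroid nodules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fnafs)
```

## The problem

Thyroid nodules are triaged preoperatively by fine-needle aspiration (FNA)
cytology, graded on the six-level Bethesda scale (VI malignant, V suspicious
for malignancy, IV follicular neoplasm, III AUS/FLUS, II benign, I
nondiagnostic), and — in many centres, routinely — by an intraoperative
frozen section (FS), reported as malignancy, suspicious for malignancy,
benign, or indeterminate. Final pathology (FP) of the resected specimen is
the binary gold standard. Two questions arise naturally:

1. How well does each test, suitably dichotomized, predict final pathology?
2. Can a *staged* rule — trust the FNA where it is near-certain, consult
   the FS otherwise — keep the accuracy of routine FS while consuming far
   fewer frozen sections?

`fnafs` implements the full evaluation: contingency tabulation,
dichotomization with the five standard accuracy metrics, the categorical
Net Reclassification Index (NRI) between paired classifiers, cascade rules
with test-usage and cost accounting, and a synthetic-cohort module so every
computation is testable without access to patient data.

## Data model

A cohort is one row per analyzed nodule-patient (bilateral or multifocal
disease is not split into multiple rows; the data model deliberately does
not attempt that reconciliation and documents it instead). Mandatory fields
are `fna_category`, `fs_category` and `outcome`, each drawn from a closed
vocabulary after case-insensitive synonym mapping — both long diagnostic
names ("suspicious for malignancy") and Bethesda numerals ("Bethesda 6",
"VI", "6") are accepted, with the synonym table versioned in one place.
Optional covariates (age, sex, nodule diameter, bilaterality,
multifocality) are empty fields when missing, never sentinel values.
`read_cohort()`/`write_cohort()` round-trip cohorts through UTF-8 CSV (or
TSV) exactly.

## Tabulation and the chi-squared comparisons

`tabulate_stage()` cross-counts a classification axis against outcome with
rows in fixed vocabulary order; `malignancy_rates()` keeps exact fractions
internally and renders percents rounded *half-up* to one decimal, the
convention used in clinical tables (base R's `round()` is banker's
rounding, which would print 96.25 as 96.2).

Cohort-characteristics comparisons use the uncorrected Pearson chi-squared
test: the uncorrected statistic is what reproduces the published
sex-by-outcome p-value of 0.013 on these strata, and a continuity-corrected
variant is available behind an option. Diameter enters as three strata
(<5, 5–10, ≥10 mm), tested as a 2×3 Pearson table; a trend test would also
be defensible but is not what the package pins.

## Dichotomization and metrics

A `scheme()` names the categories counted test-positive. The shipped
presets are the clinically conventional ones: Bethesda {V, VI} for FNA and
the unequivocal MALIGNANCY call for FS and for the combined label. They are
authoritative for reporting. `search_schemes()` exists for exploration —
over the 5 contiguous thresholds of the ordinal Bethesda scale, or all
2^k − 2 proper subsets — and makes one fact plain: the raw-accuracy-optimal
FNA threshold on the reference counts is {III,...,VI} (95.4%), *not* the
conventional {V, VI} (90.3%). The presets therefore encode clinical
convention, not a criterion optimum, and the search ranks deterministically
(criterion, then sensitivity, then fewer positive categories, then lexical
order) so its output is reproducible.

The five metrics are the standard ratios of the 2×2 table; a metric whose
denominator is empty is reported as undefined rather than silently zero,
and INDETERMINATE or Bethesda I records are ordinary negatives unless a
scheme declares them positive — dropping them would break count
conservation. Confidence intervals are Wilson score by default (well
behaved at the boundary proportions that actually occur here, e.g.
specificity = 100%), Clopper–Pearson on request; the interval method is a
package choice, as the evaluation this package reproduces reports no metric
intervals.

## The Net Reclassification Index

For paired binary classifiers the categorical NRI decomposes as

NRI = [P(up | event) − P(down | event)] + [P(down | non-event) − P(up | non-event)]
    = ΔSensitivity + ΔSpecificity.

`nri_from_marginals()` computes the point estimate from two 2×2 tables and
deliberately emits *no* interval: the paired variance depends on the joint
up/down movements, which margins do not identify. `nri_paired()` works from
record-level movements and adds the standard asymptotic variance

se² = [p_up,e + p_down,e − (p_up,e − p_down,e)²]/n_e +
      [p_up,ne + p_down,ne − (p_up,ne − p_down,ne)²]/n_ne,

a Wald 95% interval, and a two-sided normal p-value (p = 1 by convention
when nothing moves and se = 0). The paired point estimate equals the
marginal one on the induced tables for every cohort — this identity is
property-tested.

## Cascade rules, usage and cost

A `cascade_rule()` maps every first-stage category to a terminal label or
to deferral. Terminal labels live in the second-stage vocabulary, so a
combined table is four-level like FS — which is exactly what the combined
reference table implies (Bethesda VI terminal-malignant lands in the
MALIGNANCY row). `fna_sfs_rule()` is the FNA+selective-FS rule: VI is
called malignant outright, I–V defer to the frozen section. On the
reference cohort this leaves 1220 of 3807 patients (32.0%) consuming an FS,
i.e. the deferral fraction is exactly 1 − (Bethesda-VI count)/N.
`usage_and_cost()` prices three strategies (FNA only, routine FS for all,
cascade) under a `cost_model()` whose defaults — 170 USD per FNA, 20 USD
per FS — are the approximate unit charges for this clinical setting.
`flow_table()` provides the exact cross-stage counts behind a Sankey
diagram and exports renderer-agnostic node/link JSON; rendering itself is
out of scope.

## The synthetic-data module

`simulate_cohort()` draws independent records under an explicit generative
model: outcome ~ Bernoulli(prevalence); FNA category from an
outcome-conditional 6-vector; FS category from an (outcome, FNA)-conditional
(or outcome-conditional) 4-vector; optional covariates independently given
outcome. Probability vectors must sum to 1 within 1e-9. The default
configuration (`default_simulation_config()`) uses the empirical
maximum-likelihood parameters of the reconstructed reference cohort —
n = 3807, prevalence 3544/3807 ≈ 93.1%, and the observed conditional
frequencies — so the stated world of the simulator is the reference cohort
itself. `recover_parameters()` closes the loop; the simulate→recover error
shrinks at the binomial rate and is tested at two n.

What the generator does *not* emulate: covariate–category dependence (none
is reported for this setting), inter-pathologist variability, ultrasound
features, or any correlation between nodules of one patient. A green
simulation test therefore establishes correctness of the estimators under
conditional independence, not realism of every joint feature of clinical
data.

### Deterministic reconstruction

`reconstruct_cohort()` builds a patient-level cohort that reproduces, cell
for cell, the published FNA-by-outcome and FS-by-outcome tables, the
combined cascade table, and the printed FNA→FS flow counts. The
constraint arithmetic forces most joint cells: because the combined
MALIGNANCY row is the Bethesda-VI row plus the FS-MALIGNANCY calls among
I–V, the entire VI × FS × outcome block is determined, as are the FS-level
outcome totals among I–V. Residual degrees of freedom (how the unprinted
FS-MALIGNANCY/SUSPICIOUS flows split across Bethesda V–I, and where the
four indeterminate calls sit) are filled by proportional allocation with
largest-remainder rounding in fixed vocabulary order — proportional to
*capacity*, not to raw row totals: a row cannot host more FS-MALIGNANCY
calls than it has malignant patients when that FS call carries zero benign
outcomes, so raw row-total proportionality would be infeasible. The build
is fully deterministic (idempotence is tested), validates itself against
every constraint, and raises an infeasibility error naming the violated
identity when a constraint set is inconsistent. All published headline
numbers depend only on the forced margins, never on the allocation rule.

Covariates are attached deterministically: within each outcome group each
stratum is interleaved as evenly as possible, keeping every
covariate-by-outcome cross-table exact while avoiding gross correlation
with the category ordering of the records. Strata are encoded by
representative values (ages 45/65; diameters 3/7.5/12 mm) — only the
stratum is meaningful, and analyses of the reconstruction should cut at
the stratum boundaries.

A pleasant consequence: the paired NRI intervals computed from the
reconstruction match the published ones (0.138–0.227 for FNA→FS;
0.103–0.167 for FNA→cascade) because the up/down decomposition is forced
at the printed granularity.

## Numerical and interface choices

* Display rounding is half-up to one decimal; exact fractions are kept
  everywhere internally, and reported NRIs are displayed to three decimals.
* Errors are classed conditions (`fnafs_schema_error`,
  `fnafs_value_error`, `fnafs_integrity_error`, `fnafs_infeasible_error`,
  ...) so callers and the CLI can dispatch on failure kind; the CLI exits
  nonzero and names the class on stderr.
* `run_evaluate()`, `run_compare()` and `run_cascade()` assemble
  provenance-stamped report objects whose JSON and text renderings carry
  identical numbers; `inst/scripts/fnafs-cli.R` is a thin command-line
  wrapper over them (subcommands `evaluate`, `compare`, `cascade`,
  `simulate`, `fixture`).

## Limitations

The package evaluates printed-table-level and record-level cohorts of
exactly this structure; it fits no multivariable models, computes no
ROC/AUC (no continuous score exists in this workflow), and implements
neither continuous-score NRI nor IDI. Molecular triage tests and imaging
workflows upstream of FNA are out of scope. External cohorts in the same
file format are accepted by every function, but the shipped reconstruction
describes one single-centre, high-prevalence (93%) surgical population —
predictive values especially do not transport to screening populations
with lower malignancy prevalence.
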