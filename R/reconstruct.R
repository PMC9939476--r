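#' Constraints for the reference-cohort reconstruction
#'
#' The published summary counts that pin down the reference cohort: the
#' FNA-by-outcome and FS-by-outcome tables, the combined
#' (FNA+selective-FS)-by-outcome table, the printed FNA-to-FS flow counts,
#' and the outcome-conditional covariate strata. Callers may perturb the
#' returned list to explore feasibility; [reconstruct_cohort()] validates
#' the set and names the violated identity when it is inconsistent.
#'
#' @return A list of class `reconstruction_constraints` with elements
#'   `fna_by_outcome` (6x2), `fs_by_outcome` (4x2), `combined_by_outcome`
#'   (4x2), `flows`, and `covariates`.
#' @export
reference_constraints <- function() {
  fna <- matrix(c(2566, 21,
                  647, 18,
                  2, 20,
                  277, 65,
                  20, 96,
                  32, 43),
                ncol = 2L, byrow = TRUE,
                dimnames = list(fna_levels(), outcome_levels()))
  fs <- matrix(c(3334, 0,
                 80, 22,
                 126, 239,
                 4, 2),
               ncol = 2L, byrow = TRUE,
               dimnames = list(fs_levels(), outcome_levels()))
  combined <- matrix(c(3448, 21,
                       49, 16,
                       45, 224,
                       2, 2),
                     ncol = 2L, byrow = TRUE,
                     dimnames = list(fs_levels(), outcome_levels()))
  flows <- list(
    # printed FNA -> FS-MALIGNANCY counts (only these three are published)
    fna_to_fs_malignancy = c(VI = 2452, V = 608, III = 232),
    # per-Bethesda totals flowing into FS benign-or-indeterminate
    benign_or_indeterminate_by_fna = c(VI = 98, V = 38, IV = 18,
                                       III = 74, II = 100, I = 43))
  covariates <- list(
    age_lt55 = c(MALIGNANT = 2790, BENIGN = 159),
    age_ge55 = c(MALIGNANT = 754, BENIGN = 104),
    sex_f = c(MALIGNANT = 2655, BENIGN = 215),
    sex_m = c(MALIGNANT = 889, BENIGN = 48),
    diameter_lt5 = c(MALIGNANT = 812, BENIGN = 17),
    diameter_5to10 = c(MALIGNANT = 1652, BENIGN = 95),
    diameter_ge10 = c(MALIGNANT = 1080, BENIGN = 151),
    bilateral_yes = c(MALIGNANT = 735, BENIGN = NA),
    bilateral_no = c(MALIGNANT = 2809, BENIGN = NA),
    multifocal_yes = c(MALIGNANT = 1071, BENIGN = NA),
    multifocal_no = c(MALIGNANT = 2473, BENIGN = NA))
  structure(list(fna_by_outcome = fna, fs_by_outcome = fs,
                 combined_by_outcome = combined, flows = flows,
                 covariates = covariates),
            class = "reconstruction_constraints")
}

infeasible <- function(identity) {
  fnafs_abort(paste0("infeasible constraint set: ", identity),
              "fnafs_infeasible_error")
}

check_nonneg <- function(x, identity) {
  if (any(x < 0)) infeasible(identity)
  x
}

#' Deterministically reconstruct a patient-level cohort from summary counts
#'
#' Builds a cohort whose FNA-by-outcome, FS-by-outcome and cascade-combined
#' tables reproduce the constraint tables cell for cell, and whose FNA-to-FS
#' flows match the published counts. The joint cells forced by the
#' constraints (everything at the Bethesda-VI versus I-V granularity) are
#' pinned first by arithmetic; residual degrees of freedom are filled by
#' proportional-to-capacity allocation with largest-remainder rounding in
#' fixed vocabulary order — no randomness anywhere, so two builds are
#' byte-identical. The result is validated against every constraint and an
#' infeasibility error names the violated identity otherwise.
#'
#' @param constraints a [reference_constraints()]-shaped list.
#' @param covariates add the deterministic outcome-conditional covariates
#'   (age, sex, diameter, bilaterality, multifocality)? Covariate strata are
#'   encoded by representative values (ages 45/65; diameters 3/7.5/12 mm) —
#'   only the stratum is meaningful.
#' @param label cohort label.
#' @return A [cohort] (3807 records under the default constraints).
#' @export
reconstruct_cohort <- function(constraints = reference_constraints(),
                               covariates = TRUE,
                               label = "reconstructed reference cohort") {
  fna <- constraints$fna_by_outcome
  fs <- constraints$fs_by_outcome
  comb <- constraints$combined_by_outcome
  flows <- constraints$flows
  if (!is_count(fna) || !is_count(fs) || !is_count(comb)) {
    infeasible("all table counts must be nonnegative integers")
  }
  n <- sum(fna)
  if (sum(fs) != n) infeasible("total of FS table differs from FNA table")
  if (sum(comb) != n) infeasible("total of combined table differs from FNA table")
  for (o in outcome_levels()) {
    if (sum(fs[, o]) != sum(fna[, o])) {
      infeasible(sprintf("%s column total differs between FNA and FS tables", o))
    }
    if (sum(comb[, o]) != sum(fna[, o])) {
      infeasible(sprintf("%s column total differs between FNA and combined tables", o))
    }
  }

  # --- forced cells: Bethesda VI block ----------------------------------
  # combined MALIGNANCY = FNA VI (terminal) + FS-MALIGNANCY among I-V, so
  # both pieces, and hence the VI x FS x outcome cells, are determined.
  lower <- list() # FS-level outcome totals among Bethesda I-V
  lower$MALIGNANCY <- check_nonneg(
    comb["MALIGNANCY", ] - fna["VI", ],
    "combined MALIGNANCY row must dominate the FNA VI row")
  for (cc in c("SUSPICIOUS", "BENIGN", "INDETERMINATE")) {
    lower[[cc]] <- comb[cc, ]
  }
  vi <- list()
  vi$MALIGNANCY <- check_nonneg(
    fs["MALIGNANCY", ] - lower$MALIGNANCY,
    "FS MALIGNANCY row must dominate its share among Bethesda I-V")
  for (cc in c("SUSPICIOUS", "BENIGN", "INDETERMINATE")) {
    vi[[cc]] <- check_nonneg(
      fs[cc, ] - comb[cc, ],
      sprintf("FS %s row must dominate the combined %s row", cc, cc))
  }
  vi_mat <- do.call(rbind, vi)[fs_levels(), , drop = FALSE]
  if (any(colSums(vi_mat) != fna["VI", ])) {
    infeasible("Bethesda VI cells do not add up to the FNA VI row")
  }
  fl_mal <- flows$fna_to_fs_malignancy
  if (!is.na(fl_mal["VI"]) && sum(vi$MALIGNANCY) != fl_mal[["VI"]]) {
    infeasible("printed VI -> FS-MALIGNANCY flow disagrees with the tables")
  }
  benind <- flows$benign_or_indeterminate_by_fna
  if (sum(vi$BENIGN) + sum(vi$INDETERMINATE) != benind[["VI"]]) {
    infeasible("printed VI benign-or-indeterminate flow disagrees with the tables")
  }

  # --- Bethesda I-V block: FS cell sizes per row ------------------------
  rows <- setdiff(fna_levels(), "VI")
  row_tot <- rowSums(fna)[rows]
  row_mal <- fna[rows, "MALIGNANT"]
  benind_r <- benind[rows]
  if (sum(benind_r) != sum(lower$BENIGN) + sum(lower$INDETERMINATE)) {
    infeasible("benign-or-indeterminate flows disagree with combined table totals")
  }
  slack <- check_nonneg(row_tot - benind_r,
                        "benign-or-indeterminate flow exceeds an FNA row total")

  # FS-MALIGNANCY sizes: printed flows are pinned; the unprinted remainder
  # is apportioned proportional to capacity. When the FS-MALIGNANCY call
  # carries no benign outcomes, a row cannot host more such calls than it
  # has malignant patients.
  mal_cap <- if (lower$MALIGNANCY[["BENIGN"]] == 0) {
    pmin(slack, row_mal)
  } else slack
  mal_size <- stats::setNames(rep(NA_real_, length(rows)), rows)
  pinned <- intersect(names(fl_mal), rows)
  mal_size[pinned] <- fl_mal[pinned]
  if (any(mal_size[pinned] > mal_cap[pinned] + 1e-9)) {
    infeasible("a printed FNA -> FS-MALIGNANCY flow exceeds its row capacity")
  }
  free <- rows[is.na(mal_size)]
  resid <- sum(lower$MALIGNANCY) - sum(mal_size[pinned])
  if (resid < 0) infeasible("printed FS-MALIGNANCY flows exceed the column total")
  mal_size[free] <- allocate_lr(resid, weights = mal_cap[free],
                                caps = mal_cap[free])
  susp_size <- check_nonneg(slack - mal_size,
                            "FS-MALIGNANCY flow exceeds a row's non-benign slack")
  if (sum(susp_size) != sum(lower$SUSPICIOUS)) {
    infeasible("FS SUSPICIOUS sizes do not add up to the combined table")
  }
  ind_size <- allocate_lr(sum(lower$INDETERMINATE), weights = benind_r,
                          caps = benind_r)
  names(ind_size) <- rows
  ben_size <- benind_r - ind_size

  sizes <- cbind(MALIGNANCY = mal_size, SUSPICIOUS = susp_size,
                 BENIGN = ben_size, INDETERMINATE = ind_size)

  # --- Bethesda I-V block: outcome split within each FS cell ------------
  # a capped transportation fill, column by column in vocabulary order
  mal_cells <- sizes * 0
  rem <- row_mal
  for (j in seq_along(fs_levels())) {
    cc <- fs_levels()[j]
    later <- if (j < ncol(sizes)) {
      rowSums(sizes[, (j + 1L):ncol(sizes), drop = FALSE])
    } else rep(0, nrow(sizes))
    caps <- pmin(sizes[, cc], rem)
    floors <- pmax(0, rem - later)
    mal_cells[, cc] <- allocate_lr(lower[[cc]][["MALIGNANT"]],
                                   weights = caps, caps = caps,
                                   floors = floors)
    rem <- rem - mal_cells[, cc]
  }
  if (any(rem != 0)) infeasible("malignant outcomes could not be placed")
  ben_cells <- sizes - mal_cells
  for (cc in fs_levels()) {
    if (sum(ben_cells[, cc]) != lower[[cc]][["BENIGN"]]) {
      infeasible(sprintf("benign outcomes in FS %s disagree with the combined table", cc))
    }
  }

  # --- expand to records ------------------------------------------------
  fna_v <- character(0); fs_v <- character(0); out_v <- character(0)
  add <- function(k, f, s, o) {
    if (k > 0) {
      fna_v <<- c(fna_v, rep(f, k))
      fs_v <<- c(fs_v, rep(s, k))
      out_v <<- c(out_v, rep(o, k))
    }
  }
  for (cc in fs_levels()) {
    add(vi[[cc]][["MALIGNANT"]], "VI", cc, "MALIGNANT")
    add(vi[[cc]][["BENIGN"]], "VI", cc, "BENIGN")
  }
  for (r in rows) {
    for (cc in fs_levels()) {
      add(mal_cells[r, cc], r, cc, "MALIGNANT")
      add(ben_cells[r, cc], r, cc, "BENIGN")
    }
  }
  co <- cohort(fna_category = fna_v, fs_category = fs_v, outcome = out_v,
               patient_id = sprintf("P%04d", seq_along(fna_v)),
               label = label)
  if (covariates && !is.null(constraints$covariates)) {
    co <- add_reference_covariates(co, constraints$covariates)
  }

  # --- validate the build against every constraint ----------------------
  if (!all(tabulate_stage(co, "fna")$counts[fna_levels(), ] == fna)) {
    infeasible("reconstructed FNA table mismatch")
  }
  if (!all(tabulate_stage(co, "fs")$counts[fs_levels(), ] == fs)) {
    infeasible("reconstructed FS table mismatch")
  }
  casc <- apply_cascade(co, fna_sfs_rule())
  if (!all(tabulate_stage(casc, "combined")$counts[fs_levels(), ] == comb)) {
    infeasible("reconstructed combined table mismatch")
  }
  co
}

# deterministic outcome-conditional covariates: within each outcome group
# (cohort order) each stratum is interleaved as evenly as possible, keeping
# the covariate-by-outcome cross-tables exact while avoiding gross
# covariate-category correlation
add_reference_covariates <- function(co, cov) {
  n <- nrow(co)
  age <- integer(n); sex <- character(n); diam <- numeric(n)
  bilat <- rep(NA, n); multi <- rep(NA, n)
  for (o in outcome_levels()) {
    idx <- which(co$outcome == o)
    age[idx] <- spread_levels(c(45L, 65L),
                              c(cov$age_lt55[[o]], cov$age_ge55[[o]]))
    sex[idx] <- spread_levels(c("F", "M"),
                              c(cov$sex_f[[o]], cov$sex_m[[o]]))
    diam[idx] <- spread_levels(c(3, 7.5, 12),
                               c(cov$diameter_lt5[[o]],
                                 cov$diameter_5to10[[o]],
                                 cov$diameter_ge10[[o]]))
    if (o == "MALIGNANT" && !is.na(cov$bilateral_yes[[o]])) {
      bilat[idx] <- spread_levels(c(TRUE, FALSE),
                                  c(cov$bilateral_yes[[o]],
                                    cov$bilateral_no[[o]]))
      multi[idx] <- spread_levels(c(TRUE, FALSE),
                                  c(cov$multifocal_yes[[o]],
                                    cov$multifocal_no[[o]]))
    }
  }
  co$age_years <- age
  co$sex <- factor(sex, levels = c("F", "M"))
  co$diameter_mm <- diam
  co$bilateral <- as.logical(bilat)
  co$multifocal <- as.logical(multi)
  co
}

.fnafs_cache <- new.env(parent = emptyenv())

#' The 3807-patient reconstructed reference cohort
#'
#' Convenience wrapper: [reconstruct_cohort()] under the default
#' [reference_constraints()], cached after the first build (the
#' reconstruction is deterministic, so the cache is safe).
#'
#' @param covariates include the deterministic covariates.
#' @return A [cohort] of 3807 records with 93.1% malignancy prevalence.
#' @export
reference_cohort <- function(covariates = TRUE) {
  key <- if (covariates) "ref_cov" else "ref_nocov"
  if (is.null(.fnafs_cache[[key]])) {
    .fnafs_cache[[key]] <- reconstruct_cohort(covariates = covariates)
  }
  .fnafs_cache[[key]]
}
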