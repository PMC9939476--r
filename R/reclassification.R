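#' Categorical Net Reclassification Index
#'
#' The NRI between two binary classifiers of the same cohort is the net
#' proportion of events (malignant nodules) reclassified toward positive
#' plus the net proportion of non-events reclassified toward negative. For
#' paired binary classifiers this equals the change in sensitivity plus the
#' change in specificity.
#'
#' [nri_from_marginals()] takes only the two 2x2 tables; the point estimate
#' is then identified but the paired variance is not, so no standard error,
#' interval or p-value is emitted. [nri_paired()] works from record-level
#' data and additionally returns the asymptotic standard error
#' `sqrt((pue + pde - (pue - pde)^2)/n_e + (pun + pdn - (pun - pdn)^2)/n_ne)`
#' (u = up, d = down, e = events, ne = non-events), the Wald 95% interval,
#' and the two-sided normal-test p-value.
#'
#' @param old,new [binary_table]s for the reference and the new classifier,
#'   describing the same cohort (equal totals and event counts).
#' @return An object of class `reclassification` with elements `nri`,
#'   `nri_events`, `nri_nonevents`, `pairing`, and (paired only) `se`,
#'   `ci95`, `p_value`.
#' @examples
#' fna <- binary_table(3213, 39, 331, 224)
#' fs <- binary_table(3334, 0, 210, 263)
#' nri_from_marginals(fna, fs)
#' @export
nri_from_marginals <- function(old, new) {
  stopifnot(inherits(old, "binary_table"), inherits(new, "binary_table"))
  n_old <- old$tp + old$fp + old$fn + old$tn
  n_new <- new$tp + new$fp + new$fn + new$tn
  e_old <- old$tp + old$fn
  e_new <- new$tp + new$fn
  if (n_old != n_new || e_old != e_new) {
    fnafs_abort(sprintf(
      "tables describe different cohorts (totals %d vs %d, events %d vs %d)",
      n_old, n_new, e_old, e_new), "fnafs_cohort_mismatch_error")
  }
  if (e_old == 0 || n_old - e_old == 0) {
    fnafs_abort("empty event or non-event stratum", "fnafs_stratum_error")
  }
  nri_events <- new$tp / e_new - old$tp / e_old
  nri_nonevents <- new$tn / (n_new - e_new) - old$tn / (n_old - e_old)
  structure(list(nri = nri_events + nri_nonevents,
                 nri_events = nri_events,
                 nri_nonevents = nri_nonevents,
                 se = NULL, ci95 = NULL, p_value = NULL,
                 pairing = "MARGINAL_ONLY"),
            class = "reclassification")
}

# record-level positivity of a scheme evaluated on a given stage column
stage_positive <- function(cohort, stage, scheme) {
  col <- switch(stage, fna = "fna_category", fs = "fs_category",
                combined = "combined_category",
                fnafs_abort(sprintf("unknown stage '%s'", stage),
                            "fnafs_value_error"))
  v <- cohort[[col]]
  if (is.null(v) || anyNA(v)) {
    fnafs_abort(sprintf("stage '%s' not evaluable on every record", stage),
                "fnafs_value_error")
  }
  vocab <- if (stage == "fna") fna_levels() else fs_levels()
  if (is.character(scheme)) scheme <- scheme(scheme)
  unknown <- setdiff(scheme$positive, vocab)
  if (length(unknown)) {
    fnafs_abort(sprintf("positive categories not in %s vocabulary: %s",
                        stage, paste(unknown, collapse = ", ")),
                "fnafs_value_error")
  }
  as.character(v) %in% scheme$positive
}

#' @rdname nri_from_marginals
#' @param cohort a [cohort] on which both schemes are evaluable.
#' @param old_stage,new_stage `"fna"`, `"fs"`, or `"combined"`.
#' @param old_scheme,new_scheme [scheme]s over the respective stage
#'   vocabulary.
#' @examples
#' co <- reference_cohort()
#' nri_paired(co, "fna", preset_scheme("fna"), "fs", preset_scheme("fs"))
#' @export
nri_paired <- function(cohort, old_stage, old_scheme, new_stage, new_scheme) {
  stopifnot(inherits(cohort, "cohort"))
  old_pos <- stage_positive(cohort, old_stage, old_scheme)
  new_pos <- stage_positive(cohort, new_stage, new_scheme)
  event <- cohort$outcome == "MALIGNANT"
  n_e <- sum(event)
  n_ne <- sum(!event)
  if (n_e == 0 || n_ne == 0) {
    fnafs_abort("empty event or non-event stratum", "fnafs_stratum_error")
  }
  up <- !old_pos & new_pos
  down <- old_pos & !new_pos
  pue <- sum(up & event) / n_e
  pde <- sum(down & event) / n_e
  pun <- sum(up & !event) / n_ne
  pdn <- sum(down & !event) / n_ne
  nri_events <- pue - pde
  nri_nonevents <- pdn - pun
  nri <- nri_events + nri_nonevents
  se <- sqrt((pue + pde - (pue - pde)^2) / n_e +
             (pun + pdn - (pun - pdn)^2) / n_ne)
  z <- if (se > 0) nri / se else 0
  p <- if (se > 0) 2 * stats::pnorm(-abs(z)) else 1
  structure(list(nri = nri,
                 nri_events = nri_events,
                 nri_nonevents = nri_nonevents,
                 se = se,
                 ci95 = c(nri - stats::qnorm(0.975) * se,
                          nri + stats::qnorm(0.975) * se),
                 p_value = p,
                 pairing = "PAIRED_RECORDS"),
            class = "reclassification")
}

#' @export
print.reclassification <- function(x, ...) {
  cat(sprintf("NRI = %.3f (events %+.3f, non-events %+.3f) [%s]\n",
              x$nri, x$nri_events, x$nri_nonevents, x$pairing))
  if (identical(x$pairing, "PAIRED_RECORDS")) {
    cat(sprintf("  SE %.4f, 95%% CI %.3f to %.3f, p %s\n",
                x$se, x$ci95[1L], x$ci95[2L],
                if (x$p_value < 0.001) "< 0.001"
                else sprintf("= %.3f", x$p_value)))
  }
  invisible(x)
}

#' Serialize a reclassification result to JSON
#'
#' Fields follow the usual forest-plot layout: `estimate`, `ci_low`,
#' `ci_high`, `p`, plus both NRI components.
#'
#' @param x a `reclassification` result.
#' @param path optional destination; when `NULL` the JSON string is
#'   returned.
#' @export
reclassification_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "reclassification"))
  obj <- list(estimate = x$nri,
              nri_events = x$nri_events,
              nri_nonevents = x$nri_nonevents,
              ci_low = if (is.null(x$ci95)) NULL else x$ci95[1L],
              ci_high = if (is.null(x$ci95)) NULL else x$ci95[2L],
              p = x$p_value,
              pairing = x$pairing)
  obj <- obj[!vapply(obj, is.null, logical(1L))]
  if (is.null(path)) {
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}
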