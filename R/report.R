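# preset -> (stage, scheme, cascade?) resolution shared by the run_* surface
resolve_preset <- function(cohort, preset, rule = fna_sfs_rule(),
                           custom_scheme = NULL, custom_stage = "fna") {
  if (!is.null(custom_scheme)) {
    if (is.character(custom_scheme)) custom_scheme <- scheme(custom_scheme)
    return(list(stage = custom_stage, scheme = custom_scheme,
                cohort = cohort, name = custom_scheme$name))
  }
  if (!preset %in% c("fna", "fs", "cascade")) {
    fnafs_abort(sprintf("unknown preset '%s'", preset), "fnafs_value_error")
  }
  sc <- preset_scheme(preset)
  st <- switch(preset, fna = "fna", fs = "fs", cascade = "combined")
  if (preset == "cascade" && is.null(cohort$combined_category)) {
    cohort <- apply_cascade(cohort, rule)
  }
  list(stage = st, scheme = sc, cohort = cohort, name = sc$name)
}

eval_one <- function(res, ci_method = "wilson") {
  tab <- tabulate_stage(res$cohort, res$stage)
  bt <- dichotomize(tab, res$scheme)
  list(stage = res$stage, scheme = res$scheme$name,
       table = tab, binary = bt,
       metrics = compute_metrics(bt, ci_method = ci_method))
}

load_cohort_arg <- function(x, sep = ",") {
  if (inherits(x, "cohort")) {
    list(cohort = x, input = "<in-memory cohort>", digest = NA_character_)
  } else {
    list(cohort = read_cohort(x, sep = sep), input = x,
         digest = unname(tools::md5sum(x)))
  }
}

new_report <- function(kind, parts, provenance) {
  structure(c(list(kind = kind), parts, list(provenance = provenance)),
            class = "comparison_report")
}

report_provenance <- function(loaded, extra = list()) {
  c(list(input = loaded$input, input_md5 = loaded$digest,
         package = "fnafs",
         version = as.character(utils::packageVersion("fnafs")),
         date = format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    extra)
}

#' Evaluate one dichotomization scheme on a cohort
#'
#' Computes the five-metric diagnostic panel for a single preset (`"fna"`,
#' `"fs"`, `"cascade"`) or a custom scheme, from a cohort object or a
#' cohort file.
#'
#' @param cohort a [cohort] or path to a cohort file.
#' @param preset `"fna"`, `"fs"` or `"cascade"`; ignored when
#'   `custom_scheme` is given.
#' @param custom_scheme optional [scheme] (or character vector of positive
#'   categories) evaluated on `custom_stage`.
#' @param custom_stage stage for a custom scheme.
#' @param rule [cascade_rule] used when the cascade preset must be applied.
#' @param ci_method `"wilson"` or `"clopper-pearson"`.
#' @param sep delimiter when `cohort` is a path.
#' @return A `comparison_report` with one metrics panel.
#' @examples
#' run_evaluate(reference_cohort(), "fna")
#' @export
run_evaluate <- function(cohort, preset = "fna", custom_scheme = NULL,
                         custom_stage = "fna", rule = fna_sfs_rule(),
                         ci_method = "wilson", sep = ",") {
  loaded <- load_cohort_arg(cohort, sep)
  res <- resolve_preset(loaded$cohort, preset, rule, custom_scheme,
                        custom_stage)
  panel <- eval_one(res, ci_method)
  new_report("evaluate", list(schemes = stats::setNames(list(panel),
                                                        res$name)),
             report_provenance(loaded,
                               list(preset = preset, ci_method = ci_method)))
}

#' Compare two schemes on the same cohort with the NRI
#'
#' Evaluates both panels and the paired categorical Net Reclassification
#' Index from the old scheme to the new one.
#'
#' @inheritParams run_evaluate
#' @param old_preset,new_preset presets for the reference and new scheme.
#' @return A `comparison_report` with two panels and a `reclassification`.
#' @examples
#' run_compare(reference_cohort(), "fna", "fs")
#' @export
run_compare <- function(cohort, old_preset = "fna", new_preset = "fs",
                        rule = fna_sfs_rule(), ci_method = "wilson",
                        sep = ",") {
  loaded <- load_cohort_arg(cohort, sep)
  old <- resolve_preset(loaded$cohort, old_preset, rule)
  new <- resolve_preset(old$cohort, new_preset, rule) # keeps cascade columns
  old$cohort <- new$cohort
  nri <- nri_paired(new$cohort, old$stage, old$scheme, new$stage, new$scheme)
  panels <- list(eval_one(old, ci_method), eval_one(new, ci_method))
  names(panels) <- c(old$name, new$name)
  new_report("compare",
             list(schemes = panels, nri = nri),
             report_provenance(loaded,
                               list(old_preset = old_preset,
                                    new_preset = new_preset,
                                    ci_method = ci_method)))
}

#' Evaluate a cascade rule: metrics plus usage and cost
#'
#' Applies the staged rule, computes the combined-scheme metrics panel and
#' the second-test usage and cost accounting.
#'
#' @inheritParams run_evaluate
#' @param costs a [cost_model].
#' @return A `comparison_report` with the combined panel and a
#'   `cascade_usage`.
#' @examples
#' run_cascade(reference_cohort())
#' @export
run_cascade <- function(cohort, rule = fna_sfs_rule(), costs = cost_model(),
                        ci_method = "wilson", sep = ",") {
  loaded <- load_cohort_arg(cohort, sep)
  co <- apply_cascade(loaded$cohort, rule)
  res <- list(stage = "combined", scheme = preset_scheme("cascade"),
              cohort = co, name = preset_scheme("cascade")$name)
  panel <- eval_one(res, ci_method)
  usage <- usage_and_cost(co, rule, costs)
  new_report("cascade",
             list(schemes = stats::setNames(list(panel), res$name),
                  usage = usage),
             report_provenance(loaded,
                               list(rule = rule$name,
                                    ci_method = ci_method)))
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("=== fnafs %s report ===\n", x$kind))
  for (nm in names(x$schemes)) {
    cat(sprintf("\n-- %s (stage %s) --\n", nm, x$schemes[[nm]]$stage))
    print(x$schemes[[nm]]$metrics)
  }
  if (!is.null(x$nri)) {
    cat("\n-- reclassification (old -> new) --\n")
    print(x$nri)
  }
  if (!is.null(x$usage)) {
    cat("\n")
    print(x$usage)
  }
  cat(sprintf("\nprovenance: %s, fnafs %s\n", x$provenance$input,
              x$provenance$version))
  invisible(x)
}

#' Serialize a comparison report to JSON
#'
#' Every number in the JSON rendering equals the number the text rendering
#' prints (before display rounding); provenance is embedded.
#'
#' @param report a `comparison_report`.
#' @param path optional destination; when `NULL` the JSON string is
#'   returned.
#' @export
report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "comparison_report"))
  schemes <- lapply(report$schemes, function(p) {
    met <- lapply(metric_names(), function(m) {
      e <- p$metrics[[m]]
      list(estimate = e$estimate, percent = pct1(e$estimate),
           lower = e$lower, upper = e$upper, x = e$x, n = e$n)
    })
    names(met) <- metric_names()
    list(stage = p$stage,
         counts = list(tp = p$binary$tp, fp = p$binary$fp,
                       fn = p$binary$fn, tn = p$binary$tn),
         metrics = met)
  })
  obj <- list(kind = report$kind, schemes = schemes)
  if (!is.null(report$nri)) {
    obj$nri <- jsonlite::fromJSON(reclassification_json(report$nri))
  }
  if (!is.null(report$usage)) {
    u <- report$usage
    obj$usage <- list(n = u$n, deferred = u$deferred,
                      deferred_fraction = u$deferred_fraction,
                      deferred_percent = pct1(u$deferred_fraction),
                      cost_first_only = u$cost_first_only,
                      cost_both = u$cost_both,
                      cost_cascade = u$cost_cascade,
                      savings_vs_both = u$savings_vs_both,
                      currency = u$currency)
  }
  obj$provenance <- report$provenance
  if (is.null(path)) {
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
    invisible(path)
  }
}
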