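#' Staged (cascade) triage rules
#'
#' A cascade rule maps every first-stage (FNA) category either to a terminal
#' combined label — drawn from the second-stage vocabulary, so combined
#' tables are four-level like FS — or to `"DEFER"`, meaning the second-stage
#' (FS) result is consulted and copied. [fna_sfs_rule()] is the
#' FNA+selective-FS rule: Bethesda VI is called MALIGNANCY outright and
#' categories I-V defer to the frozen section.
#'
#' @param actions named character vector or list: names are first-stage
#'   categories, values are `"DEFER"` or a terminal label in `fs_levels()`.
#' @param second_stage stage consulted on deferral (only `"fs"` supported).
#' @param name free-text rule name.
#' @return An object of class `cascade_rule`.
#' @export
cascade_rule <- function(actions, second_stage = "fs", name = "cascade") {
  actions <- unlist(actions)
  if (is.null(names(actions)) || any(!nzchar(names(actions)))) {
    fnafs_abort("actions must be named by first-stage category",
                "fnafs_value_error")
  }
  if (anyDuplicated(names(actions))) {
    fnafs_abort("each first-stage category must have exactly one action",
                "fnafs_value_error")
  }
  bad <- setdiff(names(actions), fna_levels())
  if (length(bad)) {
    fnafs_abort(sprintf("unknown first-stage categories: %s",
                        paste(bad, collapse = ", ")), "fnafs_value_error")
  }
  badact <- setdiff(unname(actions), c("DEFER", fs_levels()))
  if (length(badact)) {
    fnafs_abort(sprintf("actions must be DEFER or one of {%s}; got %s",
                        paste(fs_levels(), collapse = ", "),
                        paste(badact, collapse = ", ")), "fnafs_value_error")
  }
  structure(list(actions = actions, second_stage = second_stage, name = name),
            class = "cascade_rule")
}

#' @rdname cascade_rule
#' @export
fna_sfs_rule <- function() {
  acts <- stats::setNames(rep("DEFER", 6L), fna_levels())
  acts["VI"] <- "MALIGNANCY"
  cascade_rule(acts, name = "FNA+sFS (Bethesda VI terminal, I-V defer to FS)")
}

#' @export
print.cascade_rule <- function(x, ...) {
  cat(sprintf("<cascade rule> %s\n", x$name))
  for (cat_ in names(x$actions)) {
    a <- x$actions[[cat_]]
    cat(sprintf("  %-4s -> %s\n", cat_,
                if (a == "DEFER") paste0("defer to ", x$second_stage) else a))
  }
  invisible(x)
}

#' Apply a cascade rule to a cohort
#'
#' Fills the `combined_category` column record by record (terminal label, or
#' the FS category on deferral) and flags in `fs_performed` whether the
#' second-stage test was consumed. The output cohort has the same records
#' in the same order.
#'
#' @param cohort a [cohort].
#' @param rule a [cascade_rule] covering every FNA category present.
#' @return The cohort with `combined_category` and `fs_performed` added.
#' @examples
#' co <- apply_cascade(reference_cohort(), fna_sfs_rule())
#' table(co$combined_category, co$outcome)
#' @export
apply_cascade <- function(cohort, rule = fna_sfs_rule()) {
  stopifnot(inherits(cohort, "cohort"), inherits(rule, "cascade_rule"))
  present <- unique(as.character(cohort$fna_category))
  uncovered <- setdiff(present, names(rule$actions))
  if (length(uncovered)) {
    fnafs_abort(sprintf("rule has no action for first-stage categories: %s",
                        paste(uncovered, collapse = ", ")),
                "fnafs_rule_coverage_error")
  }
  act <- rule$actions[as.character(cohort$fna_category)]
  defer <- act == "DEFER"
  combined <- ifelse(defer, as.character(cohort$fs_category), act)
  cohort$combined_category <- factor(combined, levels = fs_levels())
  cohort$fs_performed <- unname(defer)
  cohort
}

#' Unit costs for the two tests
#'
#' @param fna,fs nonnegative unit cost per specimen. Defaults are the
#'   approximate charges reported for this clinical setting: 170 USD for an
#'   FNA and 20 USD for a frozen section.
#' @param currency label only.
#' @return An object of class `cost_model`.
#' @export
cost_model <- function(fna = 170, fs = 20, currency = "USD") {
  if (is.na(fna) || is.na(fs) || fna < 0 || fs < 0) {
    fnafs_abort("unit costs must be nonnegative and present",
                "fnafs_cost_model_error")
  }
  structure(list(unit_costs = c(fna = fna, fs = fs), currency = currency),
            class = "cost_model")
}

#' Second-test usage and cost accounting for a cascade
#'
#' Reports how many records consume the second-stage test under the rule,
#' and total cost under three strategies: (a) first test only, (b) both
#' tests for everyone (routine FS), and (c) the cascade, with the savings
#' of (c) relative to (b).
#'
#' @param cohort a [cohort]; the cascade is applied if not already.
#' @param rule a [cascade_rule].
#' @param costs a [cost_model].
#' @return An object of class `cascade_usage`.
#' @examples
#' usage_and_cost(reference_cohort(), fna_sfs_rule())
#' @export
usage_and_cost <- function(cohort, rule = fna_sfs_rule(),
                           costs = cost_model()) {
  stopifnot(inherits(costs, "cost_model"))
  if (is.null(cohort$fs_performed) || is.null(cohort$combined_category)) {
    cohort <- apply_cascade(cohort, rule)
  }
  n <- nrow(cohort)
  deferred <- sum(cohort$fs_performed)
  uc <- costs$unit_costs
  if (anyNA(uc[c("fna", "fs")])) {
    fnafs_abort("missing unit cost for a consumed test",
                "fnafs_cost_model_error")
  }
  first_only <- n * uc[["fna"]]
  both <- n * (uc[["fna"]] + uc[["fs"]])
  cascade <- n * uc[["fna"]] + deferred * uc[["fs"]]
  structure(list(n = n,
                 deferred = deferred,
                 deferred_fraction = deferred / n,
                 cost_first_only = first_only,
                 cost_both = both,
                 cost_cascade = cascade,
                 savings_vs_both = both - cascade,
                 currency = costs$currency,
                 rule = rule$name),
            class = "cascade_usage")
}

#' @export
print.cascade_usage <- function(x, ...) {
  cat(sprintf("<cascade usage> %s\n", x$rule))
  cat(sprintf("  second test consumed: %d of %d (%.1f%%)\n",
              x$deferred, x$n, pct1(x$deferred_fraction)))
  cat(sprintf("  cost: first-only %s %.0f, routine-both %s %.0f, cascade %s %.0f (saves %s %.0f)\n",
              x$currency, x$cost_first_only, x$currency, x$cost_both,
              x$currency, x$cost_cascade, x$currency, x$savings_vs_both))
  invisible(x)
}

#' Cross-stage flow table
#'
#' Exact counts of records flowing from each category of one stage to each
#' category of another, split by final-pathology outcome — the counts
#' behind a Sankey diagram of diagnosis shifts (rendering is out of scope;
#' [sankey_json()] exports node/link lists any renderer can consume).
#'
#' @param cohort a [cohort] with both stage fields populated.
#' @param from,to stage names (`"fna"`, `"fs"`, `"combined"`).
#' @return An object of class `flow_table` holding a 3-way count array
#'   (from-category x to-category x outcome).
#' @examples
#' ft <- flow_table(reference_cohort(), "fna", "fs")
#' ft$counts["VI", "MALIGNANCY", ]
#' @export
flow_table <- function(cohort, from = "fna", to = "fs") {
  stopifnot(inherits(cohort, "cohort"))
  cols <- c(fna = "fna_category", fs = "fs_category",
            combined = "combined_category")
  for (st in c(from, to)) {
    if (!st %in% names(cols) || is.null(cohort[[cols[[st]]]])) {
      fnafs_abort(sprintf("stage '%s' not populated", st),
                  "fnafs_value_error")
    }
  }
  counts <- table(from = cohort[[cols[[from]]]],
                  to = cohort[[cols[[to]]]],
                  outcome = cohort$outcome)
  structure(list(from_stage = from, to_stage = to, counts = counts),
            class = "flow_table")
}

#' @export
print.flow_table <- function(x, ...) {
  cat(sprintf("<flow table> %s -> %s (n = %d)\n", x$from_stage, x$to_stage,
              sum(x$counts)))
  print(apply(x$counts, c(1L, 2L), sum))
  invisible(x)
}

#' @rdname flow_table
#' @param x a `flow_table`.
#' @param path optional destination; when `NULL` the JSON string is
#'   returned. Nodes are listed in the fixed vocabulary orders; links carry
#'   `source`, `target`, `value` and the outcome split.
#' @export
sankey_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "flow_table"))
  fromc <- dimnames(x$counts)$from
  toc <- dimnames(x$counts)$to
  nodes <- c(paste0(x$from_stage, ":", fromc), paste0(x$to_stage, ":", toc))
  links <- list()
  for (i in seq_along(fromc)) {
    for (j in seq_along(toc)) {
      v <- sum(x$counts[i, j, ])
      if (v > 0) {
        links[[length(links) + 1L]] <- list(
          source = i - 1L,
          target = length(fromc) + j - 1L,
          value = as.integer(v),
          malignant = as.integer(x$counts[i, j, "MALIGNANT"]),
          benign = as.integer(x$counts[i, j, "BENIGN"]))
      }
    }
  }
  obj <- list(nodes = lapply(nodes, function(n) list(name = n)),
              links = links)
  if (is.null(path)) {
    jsonlite::toJSON(obj, auto_unbox = TRUE)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE)
    invisible(path)
  }
}
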