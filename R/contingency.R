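#' Construct a category-by-outcome contingency table
#'
#' @param counts integer matrix, one row per category, two columns in the
#'   order `MALIGNANT`, `BENIGN`.
#' @param row_labels category labels, in display order.
#' @param source free-text provenance.
#' @return An object of class `contingency_table`.
#' @export
contingency_table <- function(counts, row_labels = rownames(counts),
                              source = "") {
  counts <- as.matrix(counts)
  if (ncol(counts) != 2L || !is_count(counts)) {
    fnafs_abort("counts must be a nonnegative integer matrix with 2 columns",
                "fnafs_value_error")
  }
  if (sum(counts) < 1L) {
    fnafs_abort("contingency table needs at least one positive entry",
                "fnafs_value_error")
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(row_labels, outcome_levels())
  structure(list(row_labels = row_labels, counts = counts,
                 source = as.character(source)[1L]),
            class = "contingency_table")
}

#' Tabulate a classification stage against final pathology
#'
#' Cross-counts one classification axis of a cohort against the binary
#' final-pathology outcome. Row order is the fixed vocabulary order
#' (Bethesda VI..I for FNA; MALIGNANCY, SUSPICIOUS, BENIGN, INDETERMINATE
#' for FS and for the combined cascade label), so outputs are diffable.
#'
#' @param cohort a [cohort].
#' @param stage `"fna"`, `"fs"`, or `"combined"` (the latter requires
#'   [apply_cascade()] to have been run on the cohort).
#' @return A `contingency_table` whose cells sum to `nrow(cohort)`.
#' @examples
#' co <- reference_cohort()
#' tabulate_stage(co, "fna")
#' @export
tabulate_stage <- function(cohort, stage = c("fna", "fs", "combined")) {
  stopifnot(inherits(cohort, "cohort"))
  if (!is.character(stage) || !stage[1L] %in% c("fna", "fs", "combined")) {
    fnafs_abort(sprintf("unknown stage '%s'", as.character(stage)[1L]),
                "fnafs_value_error")
  }
  stage <- stage[1L]
  col <- switch(stage, fna = "fna_category", fs = "fs_category",
                combined = "combined_category")
  if (is.null(cohort[[col]])) {
    fnafs_abort(sprintf("stage '%s' not populated on this cohort (column %s)",
                        stage, col), "fnafs_value_error")
  }
  tb <- table(cohort[[col]], cohort$outcome)
  contingency_table(unclass(tb)[, outcome_levels(), drop = FALSE],
                    row_labels = rownames(tb),
                    source = sprintf("%s x outcome, n=%d%s", stage,
                                     nrow(cohort),
                                     if (nzchar(attr(cohort, "label")))
                                       paste0(", ", attr(cohort, "label"))
                                     else ""))
}

#' Per-category malignancy rates
#'
#' For each category row, the fraction of records with malignant final
#' pathology, kept as an exact fraction and also rendered as a percent
#' rounded half-up to one decimal (the usual reporting convention). Rows
#' with zero total are reported as undefined (`NA`).
#'
#' @param table a `contingency_table`.
#' @return A data frame with columns `category`, `malignant`, `total`,
#'   `rate` (exact fraction) and `percent` (one-decimal display value).
#' @examples
#' malignancy_rates(tabulate_stage(reference_cohort(), "fna"))
#' @export
malignancy_rates <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  mal <- table$counts[, "MALIGNANT"]
  tot <- rowSums(table$counts)
  rate <- ifelse(tot > 0, mal / tot, NA_real_)
  data.frame(category = table$row_labels,
             malignant = as.integer(mal),
             total = as.integer(tot),
             rate = rate,
             percent = pct1(rate),
             row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Pearson chi-squared test for a contingency table
#'
#' Uncorrected Pearson chi-squared test of independence on an r-by-c count
#' matrix, with `df = (r-1)(c-1)` and the p-value from the upper tail.
#' Yates continuity correction is off by default and available via
#' `correct = TRUE`.
#'
#' @param x integer matrix of counts (or a `contingency_table`).
#' @param correct apply the continuity correction (2x2 tables only).
#' @return A list with `statistic`, `df`, `p_value` and `expected`.
#' @examples
#' # sex by final pathology
#' chi_square_test(matrix(c(2655, 215, 889, 48), 2, byrow = TRUE))
#' @export
chi_square_test <- function(x, correct = FALSE) {
  if (inherits(x, "contingency_table")) x <- x$counts
  x <- as.matrix(x)
  if (!is_count(x)) {
    fnafs_abort("counts must be nonnegative integers", "fnafs_value_error")
  }
  if (any(rowSums(x) == 0) || any(colSums(x) == 0)) {
    fnafs_abort("degenerate table: a row or column margin is zero",
                "fnafs_degenerate_error")
  }
  ht <- suppressWarnings(stats::chisq.test(x, correct = correct))
  structure(list(statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = unname(ht$p.value),
                 expected = ht$expected,
                 correct = correct),
            class = "fnafs_chisq")
}

#' @export
print.fnafs_chisq <- function(x, ...) {
  cat(sprintf("Pearson chi-squared%s: X2 = %.4g, df = %d, p = %.4g\n",
              if (x$correct) " (continuity-corrected)" else "",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("<contingency table>",
      if (nzchar(x$source)) paste0(" ", x$source) else "", "\n", sep = "")
  df <- as.data.frame(x)
  print(df, row.names = FALSE)
  cat(sprintf("  total %d\n", sum(x$counts)))
  invisible(x)
}

#' @export
as.data.frame.contingency_table <- function(x, ...) {
  r <- malignancy_rates(x)
  data.frame(category = r$category,
             malignant = x$counts[, "MALIGNANT"],
             benign = x$counts[, "BENIGN"],
             total = r$total,
             pct_malignant = r$percent,
             row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Export a contingency table
#'
#' Writes the table with explicit row and column labels either as
#' tab-separated text or as JSON.
#'
#' @param table a `contingency_table`.
#' @param path destination file.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
export_table <- function(table, path, format = c("tsv", "json")) {
  stopifnot(inherits(table, "contingency_table"))
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(as.data.frame(table), path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(
      list(row_labels = table$row_labels,
           col_labels = outcome_levels(),
           counts = unname(table$counts),
           source = table$source),
      path, auto_unbox = TRUE)
  }
  invisible(path)
}
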