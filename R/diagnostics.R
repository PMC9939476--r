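#' Dichotomization schemes
#'
#' A dichotomization scheme names the subset of a stage's categories that is
#' declared "test positive" when reducing the categorical call to a binary
#' malignant/benign prediction. The three presets pin the conventional
#' clinical choices: Bethesda V+VI positive for FNA, the unequivocal
#' MALIGNANCY call positive for FS, and likewise for the combined
#' FNA+selective-FS label.
#'
#' @param positive character vector of positive categories.
#' @param name free-text scheme name.
#' @return An object of class `dichotomization_scheme`.
#' @export
scheme <- function(positive, name = paste(positive, collapse = "+")) {
  positive <- unique(as.character(positive))
  if (length(positive) < 1L) {
    fnafs_abort("a scheme needs at least one positive category",
                "fnafs_value_error")
  }
  structure(list(positive = positive, name = name),
            class = "dichotomization_scheme")
}

#' @rdname scheme
#' @param preset one of `"fna"`, `"fs"`, `"cascade"`.
#' @export
preset_scheme <- function(preset = c("fna", "fs", "cascade")) {
  preset <- match.arg(preset)
  switch(preset,
         fna = scheme(c("V", "VI"), name = "FNA positive = Bethesda V+VI"),
         fs = scheme("MALIGNANCY", name = "FS positive = MALIGNANCY"),
         cascade = scheme("MALIGNANCY", name = "FNA+sFS positive = MALIGNANCY"))
}

#' @export
print.dichotomization_scheme <- function(x, ...) {
  cat(sprintf("<scheme> %s (positive: %s)\n", x$name,
              paste(x$positive, collapse = ", ")))
  invisible(x)
}

#' Two-by-two classification counts
#'
#' @param tp,fp,fn,tn true/false positive/negative counts against final
#'   pathology (malignant = event).
#' @return An object of class `binary_table`.
#' @export
binary_table <- function(tp, fp, fn, tn) {
  v <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (!is_count(v)) {
    fnafs_abort("tp/fp/fn/tn must be nonnegative integers", "fnafs_value_error")
  }
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = as.integer(tn)),
            class = "binary_table")
}

#' @export
print.binary_table <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, byrow = TRUE,
              dimnames = list(c("test+", "test-"), c("malignant", "benign")))
  print(m)
  invisible(x)
}

#' Collapse a contingency table to a 2x2 under a scheme
#'
#' Rows in the scheme's positive set contribute their malignant counts to TP
#' and benign counts to FP; all remaining rows (including INDETERMINATE and
#' Bethesda I — never dropped) contribute to FN and TN. The scheme must be a
#' proper, non-empty subset of the table's rows so both predicted classes
#' are realizable.
#'
#' @param table a `contingency_table`.
#' @param scheme a [scheme] (or character vector of positive categories).
#' @return A [binary_table].
#' @examples
#' dichotomize(tabulate_stage(reference_cohort(), "fna"), preset_scheme("fna"))
#' @export
dichotomize <- function(table, scheme) {
  stopifnot(inherits(table, "contingency_table"))
  if (is.character(scheme)) scheme <- scheme(scheme)
  pos <- scheme$positive
  unknown <- setdiff(pos, table$row_labels)
  if (length(unknown)) {
    fnafs_abort(sprintf("positive categories not in table: %s",
                        paste(unknown, collapse = ", ")),
                "fnafs_value_error")
  }
  if (length(pos) >= length(table$row_labels)) {
    fnafs_abort("scheme must be a proper subset of the table's categories",
                "fnafs_value_error")
  }
  ispos <- table$row_labels %in% pos
  binary_table(tp = sum(table$counts[ispos, "MALIGNANT"]),
               fp = sum(table$counts[ispos, "BENIGN"]),
               fn = sum(table$counts[!ispos, "MALIGNANT"]),
               tn = sum(table$counts[!ispos, "BENIGN"]))
}

# Wilson score or Clopper-Pearson interval for x successes out of n
prop_ci <- function(x, n, method = c("wilson", "clopper-pearson"),
                    conf = 0.95) {
  method <- match.arg(method)
  if (n == 0) return(c(NA_real_, NA_real_))
  ci <- if (method == "wilson") {
    suppressWarnings(stats::prop.test(x, n, conf.level = conf,
                                      correct = FALSE)$conf.int)
  } else {
    stats::binom.test(x, n, conf.level = conf)$conf.int
  }
  as.numeric(ci)
}

#' Diagnostic accuracy metrics from a 2x2 table
#'
#' Computes accuracy, sensitivity, specificity, positive predictive value
#' and negative predictive value with two-sided 95% confidence intervals
#' (Wilson score by default; Clopper-Pearson exact on request). A metric
#' whose denominator is zero is reported as `NA` ("undefined") while the
#' others are still returned.
#'
#' @param bt a [binary_table].
#' @param ci_method `"wilson"` or `"clopper-pearson"`.
#' @param conf_level confidence level (default 0.95).
#' @return An object of class `diag_metrics`: a list with one element per
#'   metric, each holding `estimate`, `lower`, `upper`, `x`, `n`, plus the
#'   source `counts`.
#' @examples
#' compute_metrics(binary_table(3213, 39, 331, 224))
#' @export
compute_metrics <- function(bt, ci_method = c("wilson", "clopper-pearson"),
                            conf_level = 0.95) {
  stopifnot(inherits(bt, "binary_table"))
  ci_method <- match.arg(ci_method)
  n <- bt$tp + bt$fp + bt$fn + bt$tn
  if (n == 0) fnafs_abort("empty 2x2 table", "fnafs_value_error")
  defs <- list(
    accuracy = c(bt$tp + bt$tn, n),
    sensitivity = c(bt$tp, bt$tp + bt$fn),
    specificity = c(bt$tn, bt$tn + bt$fp),
    ppv = c(bt$tp, bt$tp + bt$fp),
    npv = c(bt$tn, bt$tn + bt$fn))
  metrics <- lapply(defs, function(d) {
    x <- d[1L]; m <- d[2L]
    if (m == 0) {
      list(estimate = NA_real_, lower = NA_real_, upper = NA_real_,
           x = x, n = m)
    } else {
      ci <- prop_ci(x, m, ci_method, conf_level)
      list(estimate = x / m, lower = ci[1L], upper = ci[2L], x = x, n = m)
    }
  })
  structure(c(metrics, list(counts = bt, ci_method = ci_method,
                            conf_level = conf_level)),
            class = "diag_metrics")
}

metric_names <- function() c("accuracy", "sensitivity", "specificity",
                             "ppv", "npv")

#' @export
print.diag_metrics <- function(x, ...) {
  cat(sprintf("Diagnostic metrics (n = %d; %s 95%% CI)\n",
              x$counts$tp + x$counts$fp + x$counts$fn + x$counts$tn,
              x$ci_method))
  for (m in metric_names()) {
    e <- x[[m]]
    if (is.na(e$estimate)) {
      cat(sprintf("  %-12s undefined (0 denominator)\n", m))
    } else {
      cat(sprintf("  %-12s %5.1f%%  (%d/%d, CI %.1f-%.1f)\n", m,
                  pct1(e$estimate), e$x, e$n,
                  pct1(e$lower), pct1(e$upper)))
    }
  }
  invisible(x)
}

#' @export
as.data.frame.diag_metrics <- function(x, ...) {
  do.call(rbind, lapply(metric_names(), function(m) {
    e <- x[[m]]
    data.frame(metric = m, estimate = e$estimate, percent = pct1(e$estimate),
               lower = e$lower, upper = e$upper, x = e$x, n = e$n,
               stringsAsFactors = FALSE)
  }))
}

#' Enumerate and rank dichotomization schemes
#'
#' Exploratory search over all proper dichotomizations of a contingency
#' table: under `family = "threshold"` the contiguous top-k prefixes of the
#' (ordinal) row order — k = 1 .. r-1 schemes; under `family = "subset"`
#' every non-empty proper subset — 2^r - 2 schemes. Schemes are ranked by
#' the chosen criterion, ties broken by higher sensitivity, then fewer
#' positive categories, then lexically.
#'
#' @param table a `contingency_table`.
#' @param criterion one of `accuracy`, `sensitivity`, `specificity`, `ppv`,
#'   `npv`.
#' @param family `"threshold"` or `"subset"`.
#' @return A data frame of schemes with all five metrics, best first.
#' @export
search_schemes <- function(table, criterion = "accuracy",
                           family = c("threshold", "subset")) {
  stopifnot(inherits(table, "contingency_table"))
  family <- match.arg(family)
  if (!criterion %in% metric_names()) {
    fnafs_abort(sprintf("unknown criterion '%s'", criterion),
                "fnafs_value_error")
  }
  labs <- table$row_labels
  r <- length(labs)
  if (r < 2L) fnafs_abort("need at least 2 categories", "fnafs_value_error")
  subsets <- if (family == "threshold") {
    lapply(seq_len(r - 1L), function(k) labs[seq_len(k)])
  } else {
    masks <- seq_len(2L^r - 2L)
    lapply(masks, function(m) labs[bitwAnd(m, 2L^(seq_len(r) - 1L)) > 0])
  }
  rows <- lapply(subsets, function(pos) {
    met <- compute_metrics(dichotomize(table, scheme(pos)))
    est <- vapply(metric_names(), function(m) met[[m]]$estimate, numeric(1L))
    data.frame(positive = paste(pos, collapse = "+"),
               n_positive_categories = length(pos),
               t(est), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ord <- order(-out[[criterion]], -out$sensitivity,
               out$n_positive_categories, out$positive)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
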