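#' Build a patient cohort
#'
#' A cohort is one row per analyzed nodule-patient, carrying the preoperative
#' FNA (Bethesda) category, the intraoperative frozen-section (FS) category,
#' and the final-pathology outcome, plus optional covariates. It is stored as
#' a `data.frame` subclass so all the usual verbs work.
#'
#' @param fna_category Bethesda categories; any recognized synonym
#'   (roman or arabic numerals, long diagnostic names) is normalized to
#'   `fna_levels()`.
#' @param fs_category frozen-section calls, normalized to `fs_levels()`.
#' @param outcome final pathology, normalized to `outcome_levels()`.
#' @param patient_id unique opaque identifiers; generated (`P1`, `P2`, ...)
#'   when omitted.
#' @param age_years,sex,diameter_mm,bilateral,multifocal optional covariates;
#'   `sex` takes values `"F"`/`"M"`, the two flags are logical, and missing
#'   values are allowed.
#' @param label free-text cohort name.
#' @return An object of class `cohort` (a `data.frame`).
#' @examples
#' co <- cohort(fna_category = c("VI", "III"),
#'              fs_category = c("malignancy", "benign"),
#'              outcome = c("malignant", "benign"))
#' nrow(co)
#' @export
cohort <- function(fna_category, fs_category, outcome, patient_id = NULL,
                   age_years = NULL, sex = NULL, diameter_mm = NULL,
                   bilateral = NULL, multifocal = NULL, label = "") {
  n <- length(fna_category)
  if (n < 1L) fnafs_abort("a cohort needs at least one record", "fnafs_value_error")
  if (is.null(patient_id)) patient_id <- paste0("P", seq_len(n))
  df <- data.frame(patient_id = as.character(patient_id),
                   fna_category = as.character(fna_category),
                   fs_category = as.character(fs_category),
                   outcome = as.character(outcome),
                   stringsAsFactors = FALSE)
  opt <- list(age_years = age_years, sex = sex, diameter_mm = diameter_mm,
              bilateral = bilateral, multifocal = multifocal)
  for (nm in names(opt)) if (!is.null(opt[[nm]])) df[[nm]] <- opt[[nm]]
  as_cohort(df, label = label)
}

#' Coerce a data frame to a cohort
#'
#' Normalizes the three mandatory classification columns onto their closed
#' vocabularies (accepting the documented synonyms), parses optional
#' covariates, and enforces the cohort invariants (unique patient ids,
#' in-vocabulary categories, valid covariate ranges).
#'
#' @param df a data frame with columns `fna_category`, `fs_category`,
#'   `outcome`, optionally `patient_id` and covariates.
#' @param label free-text cohort name.
#' @return An object of class `cohort`.
#' @export
as_cohort <- function(df, label = "") {
  mandatory <- c("fna_category", "fs_category", "outcome")
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols)) {
    fnafs_abort(sprintf("missing mandatory column(s): %s",
                        paste(missing_cols, collapse = ", ")),
                "fnafs_schema_error")
  }
  if (nrow(df) < 1L) {
    fnafs_abort("a cohort needs at least one record", "fnafs_schema_error")
  }
  out <- data.frame(
    patient_id = if ("patient_id" %in% names(df)) as.character(df$patient_id)
                 else paste0("P", seq_len(nrow(df))),
    stringsAsFactors = FALSE)
  if (anyDuplicated(out$patient_id)) {
    dup <- out$patient_id[duplicated(out$patient_id)][1L]
    fnafs_abort(sprintf("duplicate patient_id '%s'", dup),
                "fnafs_integrity_error")
  }
  out$fna_category <- map_vocabulary(df$fna_category, .fna_synonyms,
                                     fna_levels(), "fna_category")
  out$fs_category <- map_vocabulary(df$fs_category, .fs_synonyms,
                                    fs_levels(), "fs_category")
  out$outcome <- map_vocabulary(df$outcome, .outcome_synonyms,
                                outcome_levels(), "outcome")

  if ("age_years" %in% names(df)) {
    age <- suppressWarnings(as.integer(df$age_years))
    if (any(!is.na(age) & age < 0)) {
      fnafs_abort("age_years must be nonnegative", "fnafs_value_error")
    }
    out$age_years <- age
  }
  if ("sex" %in% names(df)) {
    sx <- toupper(trimws(as.character(df$sex)))
    sx[sx == ""] <- NA_character_
    bad <- which(!is.na(sx) & !sx %in% c("F", "M"))
    if (length(bad)) {
      fnafs_abort(sprintf("row %d: sex must be F or M, got '%s'",
                          bad[1L], df$sex[bad[1L]]), "fnafs_value_error")
    }
    out$sex <- factor(sx, levels = c("F", "M"))
  }
  if ("diameter_mm" %in% names(df)) {
    d <- suppressWarnings(as.numeric(df$diameter_mm))
    if (any(!is.na(d) & d <= 0)) {
      fnafs_abort("diameter_mm must be positive", "fnafs_value_error")
    }
    out$diameter_mm <- d
  }
  for (flag in c("bilateral", "multifocal")) {
    if (flag %in% names(df)) {
      v <- df[[flag]]
      if (!is.logical(v)) {
        s <- tolower(trimws(as.character(v)))
        s[s == ""] <- NA_character_
        bad <- which(!is.na(s) & !s %in% c("true", "false"))
        if (length(bad)) {
          fnafs_abort(sprintf("row %d: %s must be true/false", bad[1L], flag),
                      "fnafs_value_error")
        }
        v <- s == "true"
      }
      out[[flag]] <- v
    }
  }
  if ("combined_category" %in% names(df)) {
    out$combined_category <- map_vocabulary(df$combined_category, .fs_synonyms,
                                            fs_levels(), "combined_category")
  }
  if ("fs_performed" %in% names(df)) {
    out$fs_performed <- as.logical(df$fs_performed)
  }
  structure(out, label = as.character(label)[1L],
            class = c("cohort", "data.frame"))
}

#' @export
print.cohort <- function(x, ...) {
  lbl <- attr(x, "label")
  cat(sprintf("<cohort> %d records%s\n", nrow(x),
              if (nzchar(lbl)) paste0(" - ", lbl) else ""))
  tb <- table(x$outcome)
  cat(sprintf("  final pathology: %d malignant / %d benign (prevalence %.1f%%)\n",
              tb[["MALIGNANT"]], tb[["BENIGN"]],
              100 * tb[["MALIGNANT"]] / nrow(x)))
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("  ... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' @export
summary.cohort <- function(object, ...) {
  list(n = nrow(object),
       label = attr(object, "label"),
       fna = table(object$fna_category),
       fs = table(object$fs_category),
       outcome = table(object$outcome))
}

#' Read a cohort from delimited text
#'
#' Reads a UTF-8 delimited file (comma by default, tab via `sep`) with a
#' header row naming at least the mandatory columns `fna_category`,
#' `fs_category` and `outcome`. Category tokens are matched
#' case-insensitively against the synonym tables (so `"Bethesda 6"`,
#' `"malignant (VI)"` and `"VI"` all parse to Bethesda VI). Row order is
#' preserved. Empty fields are missing covariates.
#'
#' @param path file to read.
#' @param sep field delimiter, `","` or `"\t"`.
#' @param label cohort name; defaults to the file name.
#' @return An object of class [cohort].
#' @seealso [write_cohort()] for the inverse; the pair round-trips.
#' @export
read_cohort <- function(path, sep = ",", label = basename(path)) {
  if (!file.exists(path)) {
    fnafs_abort(sprintf("no such file: %s", path), "fnafs_io_error")
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          colClasses = "character", check.names = TRUE,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                          blank.lines.skip = TRUE)
  as_cohort(df, label = label)
}

#' Write a cohort to delimited text
#'
#' Inverse of [read_cohort()]: writes canonical category labels, booleans as
#' `true`/`false`, missing covariates as empty fields, and omits optional
#' columns that are entirely absent, so that reading the file back
#' reproduces the cohort record for record.
#'
#' @param cohort a [cohort].
#' @param path destination file.
#' @param sep field delimiter, `","` or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, sep = ",") {
  stopifnot(inherits(cohort, "cohort"))
  df <- as.data.frame(cohort)
  keep <- vapply(names(df), function(nm) {
    nm %in% c("patient_id", "fna_category", "fs_category", "outcome") ||
      !all(is.na(df[[nm]]))
  }, logical(1L))
  df <- df[, keep, drop = FALSE]
  for (nm in names(df)) {
    v <- df[[nm]]
    if (is.logical(v)) {
      df[[nm]] <- ifelse(is.na(v), "", ifelse(v, "true", "false"))
    } else if (is.factor(v)) {
      df[[nm]] <- as.character(v)
    }
  }
  ok <- tryCatch({
    utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                       na = "", fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    fnafs_abort(sprintf("cannot write cohort to %s: %s",
                        path, conditionMessage(ok)), "fnafs_io_error")
  }
  invisible(path)
}
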