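#' Category vocabularies
#'
#' Closed vocabularies for the three classification axes, in the fixed
#' display order used by every table the package produces: Bethesda
#' categories VI down to I for fine-needle aspiration (FNA), the four
#' frozen-section (FS) levels, and the binary final-pathology outcome.
#'
#' @return Character vector of category labels in canonical order.
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
fna_levels <- function() c("VI", "V", "IV", "III", "II", "I")

#' @rdname vocabularies
#' @export
fs_levels <- function() c("MALIGNANCY", "SUSPICIOUS", "BENIGN", "INDETERMINATE")

#' @rdname vocabularies
#' @export
outcome_levels <- function() c("MALIGNANT", "BENIGN")

# One versioned synonym table per axis. Keys are matched after lower-casing,
# trimming and collapsing internal whitespace; both the long diagnostic names
# and roman/arabic Bethesda numerals are accepted.
.fna_synonyms <- c(
  "vi" = "VI", "v" = "V", "iv" = "IV", "iii" = "III", "ii" = "II", "i" = "I",
  "6" = "VI", "5" = "V", "4" = "IV", "3" = "III", "2" = "II", "1" = "I",
  "bethesda vi" = "VI", "bethesda v" = "V", "bethesda iv" = "IV",
  "bethesda iii" = "III", "bethesda ii" = "II", "bethesda i" = "I",
  "bethesda 6" = "VI", "bethesda 5" = "V", "bethesda 4" = "IV",
  "bethesda 3" = "III", "bethesda 2" = "II", "bethesda 1" = "I",
  "malignant" = "VI", "malignant (vi)" = "VI",
  "suspicious for malignancy" = "V", "sfm" = "V", "sfm (v)" = "V",
  "follicular neoplasm" = "IV", "suspicious for follicular neoplasm" = "IV",
  "fn/sfn" = "IV", "fn/sfn (iv)" = "IV",
  "aus/flus" = "III", "aus" = "III", "flus" = "III", "aus/flus (iii)" = "III",
  "atypia of undetermined significance" = "III",
  "follicular lesion of undetermined significance" = "III",
  "benign" = "II", "benign (ii)" = "II",
  "nondiagnostic" = "I", "unsatisfactory" = "I",
  "nondiagnostic/unsatisfactory" = "I",
  "nondiagnostic/unsatisfactory (i)" = "I"
)

.fs_synonyms <- c(
  "malignancy" = "MALIGNANCY", "malignant" = "MALIGNANCY",
  "suspicious" = "SUSPICIOUS", "suspicious for malignancy" = "SUSPICIOUS",
  "benign" = "BENIGN",
  "indeterminate" = "INDETERMINATE"
)

.outcome_synonyms <- c(
  "malignant" = "MALIGNANT", "malignancy" = "MALIGNANT",
  "benign" = "BENIGN"
)

.norm_token <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

# Map raw tokens onto a closed vocabulary; unmappable tokens raise a value
# error naming the first offending file row (1-based data rows).
map_vocabulary <- function(x, synonyms, levels, field) {
  key <- .norm_token(x)
  out <- unname(synonyms[key])
  bad <- which(is.na(out) | key == "")
  if (length(bad)) {
    fnafs_abort(
      sprintf("row %d: cannot map %s value '%s' onto {%s}",
              bad[1L], field, as.character(x)[bad[1L]],
              paste(levels, collapse = ", ")),
      "fnafs_value_error")
  }
  factor(out, levels = levels)
}
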