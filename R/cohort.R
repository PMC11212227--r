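#' Read a cohort CSV
#'
#' Reads a cohort table in the Pima schema (RFC-4180 CSV with a header row).
#' Column order is free; Kaggle-dialect column names (`Glucose`, `Insulin`,
#' `SkinThickness`, `BloodPressure`, `DiabetesPedigreeFunction`) are accepted
#' as aliases. Empty cells load as missing (`NA`). The outcome column is
#' optional.
#'
#' @param path CSV file path.
#' @param schema a [feature_schema()].
#' @return a data.frame with the schema's feature columns (numeric) and, if
#'   present in the file, the outcome column; attribute `"schema"` carries
#'   the schema.
#' @export
read_cohort <- function(path, schema = pima_schema()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = "")
  names(raw) <- canonical_features(names(raw))
  has_outcome <- schema$outcome %in% names(raw)
  expected <- c(schema$features, if (has_outcome) schema$outcome)
  missing_cols <- setdiff(schema$features, names(raw))
  extra_cols <- setdiff(names(raw), expected)
  if (length(missing_cols) || length(extra_cols)) {
    stop("schema mismatch",
         if (length(missing_cols)) paste0("; missing column(s): ",
                                          paste(missing_cols, collapse = ", ")),
         if (length(extra_cols)) paste0("; unexpected column(s): ",
                                        paste(extra_cols, collapse = ", ")))
  }
  out <- raw[, expected, drop = FALSE]
  for (col in expected) {
    vals <- out[[col]]
    parsed <- suppressWarnings(as.numeric(vals))
    bad <- which(!is.na(vals) & is.na(parsed))
    if (length(bad))
      stop("non-numeric value ", dQuote(vals[bad[1]]), " in column ", col,
           ", row ", bad[1])
    out[[col]] <- parsed
  }
  if (has_outcome) {
    y <- out[[schema$outcome]]
    if (!all(is.na(y) | y %in% c(0, 1)))
      stop("outcome column must be binary 0/1")
  }
  if (any(!is.na(out$Age) & out$Age == 0))
    warning("Age = 0 found: invalid in this cohort (ages start at 21); ",
            "use knowledge_filter() to drop such rows")
  attr(out, "schema") <- schema
  out
}

#' Write a cohort CSV
#'
#' Missing cells are written as empty fields, so a written table re-read with
#' [read_cohort()] reproduces values and missingness exactly.
#'
#' @param table cohort data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path) {
  out <- table
  for (f in names(out)) {
    if (is.numeric(out[[f]])) {
      # %.17g guarantees the double parses back to the identical value
      x <- sprintf("%.17g", out[[f]])
      x[is.na(out[[f]])] <- ""
      out[[f]] <- x
    }
  }
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Mark physiologically implausible zeros as missing
#'
#' In the Pima dialect, zero values of glucose, blood pressure, skin
#' thickness, insulin and BMI encode missing measurements. This converts
#' exact zeros in the listed features to `NA`; all other cells (including
#' zero pregnancies, which are plausible) are untouched. Idempotent.
#'
#' @param table cohort data.frame.
#' @param features feature names whose zeros are implausible; defaults to
#'   the shipped knowledge base's set.
#' @return a new data.frame with zeros in `features` replaced by `NA`.
#' @export
mark_implausible_zeros <- function(table,
    features = default_pima_knowledge()$implausible_zero_features) {
  features <- canonical_features(features)
  unknown <- setdiff(features, names(table))
  if (length(unknown))
    stop("unknown feature(s): ", paste(unknown, collapse = ", "))
  out <- table
  for (f in features) {
    z <- !is.na(out[[f]]) & out[[f]] == 0
    out[[f]][z] <- NA_real_
  }
  out
}
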