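#' Feature schema for a clinical cohort table
#'
#' A schema names the features of a cohort, their measurement units, and the
#' binary outcome column. All knowledge-base components (intervals, rules,
#' causal structure, formulas) refer to features through a shared schema.
#'
#' @param features character vector of feature names (unique).
#' @param units named character vector of measurement units, one per feature.
#' @param outcome name of the binary outcome column.
#' @return An object of class `feature_schema`.
#' @export
feature_schema <- function(features, units = NULL, outcome = "Outcome") {
  stopifnot(is.character(features), length(features) >= 1)
  if (anyDuplicated(features)) stop("feature names must be unique")
  if (outcome %in% features) stop("outcome column must not be a feature")
  if (is.null(units)) {
    units <- stats::setNames(rep("", length(features)), features)
  }
  structure(
    list(features = features, units = units, outcome = outcome),
    class = "feature_schema"
  )
}

#' The Pima Indians diabetes schema
#'
#' Eight clinical features measured on women aged 21 and above, plus a binary
#' outcome indicating a diabetes diagnosis within five years. `G120` and
#' `I120` are the 2-hour glucose and insulin measurements of an oral glucose
#' tolerance test (OGTT); `DPF` is the diabetes pedigree function, a family
#' history likelihood score.
#'
#' @return A `feature_schema` with features Pregnancies, G120, BP, ST, I120,
#'   BMI, DPF, Age and outcome column `Outcome`.
#' @export
pima_schema <- function() {
  feature_schema(
    features = c("Pregnancies", "G120", "BP", "ST", "I120", "BMI", "DPF", "Age"),
    units = c(
      Pregnancies = "count", G120 = "mg/dL", BP = "mmHg", ST = "mm",
      I120 = "uU/ml", BMI = "kg/m^2", DPF = "dimensionless", Age = "years"
    ),
    outcome = "Outcome"
  )
}

# Accepted column-name aliases (Kaggle dialect and text variants).
.pima_aliases <- c(
  Glucose = "G120", Insulin = "I120", SkinThickness = "ST",
  BloodPressure = "BP", DiabetesPedigreeFunction = "DPF",
  SK = "ST", Pregnant = "Pregnancies"
)

#' Canonicalise feature names
#'
#' Maps accepted aliases (e.g. `Glucose`, `SkinThickness`, `SK`, `Pregnant`)
#' to the canonical Pima schema names; names already canonical pass through.
#'
#' @param x character vector of feature names.
#' @return character vector of canonical names.
#' @export
canonical_features <- function(x) {
  hit <- x %in% names(.pima_aliases)
  x[hit] <- unname(.pima_aliases[x[hit]])
  x
}

#' @export
print.feature_schema <- function(x, ...) {
  cat("Feature schema:", length(x$features), "features, outcome =",
      x$outcome, "\n")
  for (f in x$features) cat(sprintf("  %-12s [%s]\n", f, x$units[[f]]))
  invisible(x)
}
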