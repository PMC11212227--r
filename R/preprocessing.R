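#' Median imputation
#'
#' Fills each missing cell of `apply_to` with the median of the observed
#' values of that feature in `train`. Fitting on the training fold only and
#' applying to both folds avoids information leakage; pass the same table
#' twice for whole-table imputation.
#'
#' @param train training cohort data.frame (non-empty).
#' @param apply_to cohort data.frame to fill; defaults to `train`.
#' @param features columns to impute; defaults to all shared numeric columns.
#' @return `apply_to` with missing cells filled.
#' @export
median_impute <- function(train, apply_to = train, features = NULL) {
  if (nrow(train) == 0) stop("training table is empty")
  if (is.null(features))
    features <- intersect(names(train), names(apply_to))
  out <- apply_to
  for (f in features) {
    if (!anyNA(out[[f]])) next
    obs <- train[[f]][!is.na(train[[f]])]
    if (length(obs) == 0)
      stop("feature ", f, " has no observed values in the training table")
    out[[f]][is.na(out[[f]])] <- stats::median(obs)
  }
  out
}

#' Discretise a cohort into ordinal clinical categories
#'
#' Maps each numeric value to the label of the interval containing it in the
#' scheme. Missing cells stay missing. Columns not covered by the scheme
#' (e.g. the outcome) pass through unchanged.
#'
#' @param table cohort data.frame.
#' @param scheme a [discretisation_scheme()].
#' @return a data.frame of ordered factors (plus untouched columns), with
#'   attribute `"scheme"`.
#' @export
discretise <- function(table, scheme) {
  out <- table
  for (f in intersect(scheme_features(scheme), names(table))) {
    d <- scheme$intervals[[f]]
    x <- table[[f]]
    lab <- rep(NA_character_, length(x))
    for (i in seq_len(nrow(d))) {
      hit <- !is.na(x) & .in_interval(x, d[i, ])
      lab[hit] <- d$label[i]
    }
    uncovered <- which(!is.na(x) & is.na(lab))
    if (length(uncovered))
      stop("value ", x[uncovered[1]], " of feature ", f,
           " lies outside all intervals (row ", uncovered[1], ")")
    out[[f]] <- factor(lab, levels = d$label, ordered = TRUE)
  }
  attr(out, "scheme") <- scheme
  out
}

#' One-hot encode a categorical table
#'
#' Expands every factor column into one 0/1 indicator column per category,
#' named `feature=label`. Each feature's block then has exactly one 1 per
#' row. Non-factor columns (e.g. the outcome) pass through.
#'
#' @param table categorical data.frame (no missing cells in factor columns).
#' @return a numeric data.frame of indicators.
#' @export
one_hot <- function(table) {
  cols <- list()
  for (f in names(table)) {
    x <- table[[f]]
    if (!is.factor(x)) { cols[[f]] <- x; next }
    if (anyNA(x))
      stop("feature ", f, " has missing cells; impute before one-hot encoding")
    for (lv in levels(x)) {
      cols[[paste0(f, "=", lv)]] <- as.integer(x == lv)
    }
  }
  as.data.frame(cols, check.names = FALSE)
}

#' Min-max scaling to [0, 1]
#'
#' Scales each feature by the training-fold range:
#' `(x - min_train) / (max_train - min_train)`. Values outside the training
#' range are clipped to `[0, 1]`; a feature constant in training maps to 0
#' with a warning.
#'
#' @param train training cohort data.frame (no missing cells in `features`).
#' @param apply_to data.frame to scale; defaults to `train`.
#' @param features columns to scale; defaults to all shared numeric columns
#'   except `exclude`.
#' @param exclude columns never scaled (default the outcome column).
#' @return `apply_to` with scaled features.
#' @export
minmax_scale <- function(train, apply_to = train, features = NULL,
                         exclude = "Outcome") {
  if (is.null(features))
    features <- setdiff(intersect(names(train), names(apply_to)), exclude)
  out <- apply_to
  for (f in features) {
    if (!is.numeric(train[[f]])) next
    lo <- min(train[[f]]); hi <- max(train[[f]])
    if (is.na(lo) || is.na(hi))
      stop("feature ", f, " has missing cells; impute before scaling")
    if (hi == lo) {
      warning("feature ", f, " is constant in training; mapped to 0")
      out[[f]] <- rep(0, nrow(out))
    } else {
      out[[f]] <- pmin(1, pmax(0, (out[[f]] - lo) / (hi - lo)))
    }
  }
  out
}

#' Keep only rows where all causal root features are observed
#'
#' Bayesian-network imputation conditions on the DAG's root features
#' (pregnancies, age, BMI, family history in the default structure), so
#' analysis is restricted to records observing all of them.
#'
#' @param table cohort (numeric or categorical) data.frame.
#' @param structure a [causal_structure()].
#' @return the subset data.frame; attribute `"retained_fraction"` reports
#'   the fraction of rows kept.
#' @export
filter_root_complete <- function(table, structure) {
  roots <- structure_roots(structure)
  roots <- intersect(roots, names(table))
  keep <- rep(TRUE, nrow(table))
  for (f in roots) keep <- keep & !is.na(table[[f]])
  out <- table[keep, , drop = FALSE]
  attr(out, "retained_fraction") <-
    if (nrow(table) == 0) 1 else sum(keep) / nrow(table)
  attr(out, "scheme") <- attr(table, "scheme")
  out
}

#' Filter records violating knowledge-base constraints
#'
#' Removes rows whose observed values fall outside the plausible range
#' covered by the discretisation scheme (e.g. Age = 0 in a cohort of adults,
#' or a negative physical quantity) and itemises every violation.
#'
#' @param table cohort data.frame.
#' @param kb a [knowledge_base()].
#' @return a list with `table` (rows kept) and `report` (data.frame with
#'   columns `row`, `feature`, `value`).
#' @export
knowledge_filter <- function(table, kb) {
  bad_rows <- integer(0)
  rep_row <- integer(0); rep_feat <- character(0); rep_val <- numeric(0)
  for (f in intersect(scheme_features(kb$scheme), names(table))) {
    rg <- scheme_range(kb$scheme, f)
    x <- table[[f]]
    below <- if (rg$lower_closed) x < rg$lower else x <= rg$lower
    above <- if (rg$upper_closed) x > rg$upper else x >= rg$upper
    viol <- which(!is.na(x) & (below | above))
    if (length(viol)) {
      rep_row <- c(rep_row, viol)
      rep_feat <- c(rep_feat, rep(f, length(viol)))
      rep_val <- c(rep_val, x[viol])
      bad_rows <- union(bad_rows, viol)
    }
  }
  report <- data.frame(row = rep_row, feature = rep_feat, value = rep_val,
                       stringsAsFactors = FALSE)
  report <- report[order(report$row), , drop = FALSE]
  keep <- setdiff(seq_len(nrow(table)), bad_rows)
  list(table = table[keep, , drop = FALSE], report = report)
}
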