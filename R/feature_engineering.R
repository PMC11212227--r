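#' Causal feature selection
#'
#' Keeps every feature adjacent to the target in the causal DAG (a direct
#' parent or child of the outcome) and drops features connected to the
#' target only through other features, recording the mediating path as the
#' reason. In the default diabetes structure this drops exactly skin
#' thickness (ST), which relates to the outcome only through obesity (BMI).
#'
#' An alternative `"markov_blanket"` mode keeps parents, children and
#' co-parents of the target's children.
#'
#' @param structure a [causal_structure()].
#' @param target target node (default the structure's outcome).
#' @param mode `"adjacent"` (default) or `"markov_blanket"`.
#' @return a list of class `feature_subset` with `kept` (character vector)
#'   and `dropped` (data.frame `feature`, `reason`).
#' @export
causal_feature_select <- function(structure, target = structure$outcome,
                                  mode = c("adjacent", "markov_blanket")) {
  mode <- match.arg(mode)
  if (!target %in% structure$nodes) stop("target node not in structure: ", target)
  feats <- setdiff(structure$nodes, target)
  parents <- structure_parents(structure, target)
  children <- structure_children(structure, target)
  keep <- union(parents, children)
  if (mode == "markov_blanket") {
    coparents <- unlist(lapply(children, structure_parents,
                               structure = structure))
    keep <- setdiff(union(keep, coparents), target)
  }
  dropped <- setdiff(feats, keep)
  reasons <- vapply(dropped, function(f) {
    p <- .undirected_path(structure, f, target)
    if (is.null(p)) "no path to target"
    else paste0("linked to ", target, " only via ",
                paste(p[-c(1, length(p))], collapse = " -> "))
  }, character(1))
  out <- list(kept = keep,
              dropped = data.frame(feature = dropped,
                                   reason = unname(reasons),
                                   stringsAsFactors = FALSE))
  class(out) <- "feature_subset"
  out
}

# Shortest undirected path between two nodes (BFS); NULL if none.
.undirected_path <- function(structure, from, to) {
  adj <- function(n) unique(c(structure_children(structure, n),
                              structure_parents(structure, n)))
  prev <- stats::setNames(rep(NA_character_, length(structure$nodes)),
                          structure$nodes)
  seen <- from
  queue <- from
  while (length(queue)) {
    n <- queue[1]; queue <- queue[-1]
    if (n == to) {
      path <- to
      while (!is.na(prev[path[1]])) path <- c(prev[path[1]], path)
      return(path)
    }
    for (m in setdiff(adj(n), seen)) {
      prev[m] <- n
      seen <- c(seen, m)
      queue <- c(queue, m)
    }
  }
  NULL
}

#' @export
print.feature_subset <- function(x, ...) {
  cat("Kept:", paste(x$kept, collapse = ", "), "\n")
  if (nrow(x$dropped)) {
    cat("Dropped:\n")
    for (i in seq_len(nrow(x$dropped)))
      cat("  ", x$dropped$feature[i], "-", x$dropped$reason[i], "\n")
  } else cat("Dropped: none\n")
  invisible(x)
}

#' Compute a composite clinical index column
#'
#' Evaluates `intercept + sum(coefficient * feature)` per row and appends it
#' as a new column named after the formula. With `replace = TRUE` the
#' constituent feature columns are removed (the index is used instead of
#' them). Every row must observe all constituents; restrict the table first
#' if needed.
#'
#' @param table cohort data.frame.
#' @param formula a [composite_formula()]; default the Stumvoll index.
#' @param replace drop the constituent columns (default `FALSE`).
#' @return the table with the new column.
#' @export
compute_index <- function(table, formula = stumvoll_formula(),
                          replace = FALSE) {
  feats <- names(formula$coefficients)
  missing_cols <- setdiff(feats, names(table))
  if (length(missing_cols))
    stop("table lacks constituent column(s): ",
         paste(missing_cols, collapse = ", "))
  val <- rep(formula$intercept, nrow(table))
  for (f in feats) {
    x <- table[[f]]
    bad <- which(is.na(x))
    if (length(bad))
      stop("row ", bad[1], " is missing constituent feature ", f)
    val <- val + formula$coefficients[[f]] * x
  }
  out <- table
  out[[formula$name]] <- val
  if (replace) out <- out[, setdiff(names(out), feats), drop = FALSE]
  out
}

#' Permutation feature importance
#'
#' Importance of a feature = baseline metric minus the mean metric over
#' `n_repeats` independent within-column shuffles of that feature. Uses
#' balanced accuracy by default (robust to class imbalance). Deterministic
#' under `seed`.
#'
#' @param model a fitted predictor accepted by [predict_prob()].
#' @param table feature data.frame.
#' @param labels 0/1 outcome vector.
#' @param metric one of `"balanced_accuracy"`, `"accuracy"`, `"f1"`,
#'   `"roc_auc"`.
#' @param n_repeats number of shuffles per feature (>= 1).
#' @param seed RNG seed.
#' @return data.frame `feature`, `importance`, sorted descending.
#' @export
permutation_importance <- function(model, table, labels,
                                   metric = "balanced_accuracy",
                                   n_repeats = 10, seed = 1) {
  if (n_repeats < 1) stop("n_repeats must be >= 1")
  metric <- match.arg(metric,
                      c("balanced_accuracy", "accuracy", "f1", "roc_auc"))
  score <- function(tab) {
    p <- predict_prob(model, tab)
    m <- compute_metrics(labels, as.integer(p >= 0.5), p)
    m[[metric]]
  }
  base <- score(table)
  set.seed(seed)
  imp <- vapply(names(table), function(f) {
    drops <- vapply(seq_len(n_repeats), function(k) {
      tab <- table
      tab[[f]] <- sample(tab[[f]])
      base - score(tab)
    }, numeric(1))
    mean(drops)
  }, numeric(1))
  out <- data.frame(feature = names(imp), importance = unname(imp),
                    stringsAsFactors = FALSE)
  out[order(-out$importance), , drop = FALSE]
}
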