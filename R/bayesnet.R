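#' Fitted Bayesian network
#'
#' A causal DAG plus one conditional probability table (CPT) per node over
#' the node's categories for every configuration of its parents' categories.
#' Used for missing-data imputation and for synthetic cohort sampling.
#'
#' @param structure a [causal_structure()].
#' @param cpts named list, one per node: `list(parents, levels,
#'   parent_levels, prob)` with `prob` an `n_config x n_levels` matrix whose
#'   rows are distributions; parent configurations are in
#'   `expand.grid(parent_levels)` order (first parent fastest).
#' @return an object of class `fitted_bayesnet`.
#' @export
fitted_bayesnet <- function(structure, cpts) {
  ord <- topological_order(structure)
  if (is.null(ord)) stop("structure has a cycle")
  missing_nodes <- setdiff(structure$nodes, names(cpts))
  if (length(missing_nodes))
    stop("no CPT for node(s): ", paste(missing_nodes, collapse = ", "))
  for (n in names(cpts)) {
    p <- cpts[[n]]$prob
    if (any(p < 0) || any(abs(rowSums(p) - 1) > 1e-9))
      stop("CPT rows for node ", n, " are not distributions")
  }
  out <- list(structure = structure, cpts = cpts, order = ord)
  class(out) <- "fitted_bayesnet"
  out
}

# Row indices into a CPT's prob matrix for a data.frame of parent columns
# (character or factor). Returns 1 for all rows when there are no parents.
.config_index <- function(cpt, parent_values) {
  if (length(cpt$parents) == 0) return(rep(1L, nrow(parent_values)))
  idx <- rep(1L, nrow(parent_values))
  mult <- 1L
  for (p in cpt$parents) {
    lv <- cpt$parent_levels[[p]]
    pos <- match(as.character(parent_values[[p]]), lv)
    if (anyNA(pos)) stop("value of parent ", p, " outside its category set")
    idx <- idx + (pos - 1L) * mult
    mult <- mult * length(lv)
  }
  idx
}

# Category levels of each node: scheme levels for features, 0/1 for outcome.
.node_levels <- function(structure, scheme, outcome_levels = c("0", "1")) {
  out <- list()
  for (n in structure$nodes) {
    out[[n]] <- if (n == structure$outcome) outcome_levels
                else scheme_levels(scheme, n)
  }
  out
}

#' Fit conditional probability tables from a categorical table
#'
#' Maximum-likelihood CPT estimation with Laplace smoothing:
#' `(count + smoothing) / (family count + smoothing * n_categories)`. Each
#' node uses the rows where the node and all its parents are observed
#' (complete cases per family). A parent configuration never observed gives
#' the uniform distribution when `smoothing > 0`.
#'
#' @param train categorical data.frame (ordered factors from [discretise()],
#'   outcome column 0/1).
#' @param structure a [causal_structure()].
#' @param smoothing Laplace pseudo-count (default 1).
#' @param scheme the discretisation scheme defining category sets; defaults
#'   to the scheme attached to `train` by [discretise()].
#' @return a [fitted_bayesnet()].
#' @export
fit_cpts <- function(train, structure, smoothing = 1,
                     scheme = attr(train, "scheme")) {
  if (nrow(train) == 0) stop("training table is empty")
  if (is.null(scheme)) stop("no discretisation scheme supplied or attached")
  levs <- .node_levels(structure, scheme)
  cpts <- list()
  for (n in structure$nodes) {
    parents <- structure_parents(structure, n)
    nl <- levs[[n]]
    pl <- levs[parents]
    n_config <- prod(vapply(pl, length, integer(1)))
    if (length(parents) == 0) n_config <- 1L
    fam <- c(n, parents)
    ok <- stats::complete.cases(train[, fam, drop = FALSE])
    sub <- train[ok, , drop = FALSE]
    counts <- matrix(0, nrow = n_config, ncol = length(nl))
    if (nrow(sub) > 0) {
      ci <- .config_index(list(parents = parents, parent_levels = pl),
                          sub[, parents, drop = FALSE])
      vi <- match(as.character(sub[[n]]), nl)
      if (anyNA(vi)) stop("values of node ", n, " outside its category set")
      counts <- unclass(table(factor(ci, levels = seq_len(n_config)),
                              factor(vi, levels = seq_along(nl))))
      dimnames(counts) <- NULL
    }
    prob <- (counts + smoothing) /
      (rowSums(counts) + smoothing * length(nl))
    if (smoothing == 0) {
      zero <- rowSums(counts) == 0
      prob[zero, ] <- NA_real_  # unobserved configuration, no estimate
    }
    cpts[[n]] <- list(parents = parents, levels = nl, parent_levels = pl,
                      prob = prob)
  }
  fitted_bayesnet(structure, cpts)
}

#' Per-feature median category of a categorical table
#'
#' The category at the median ordinal rank of the observed values; with an
#' even count and two middle ranks, the lower (less extreme relative to the
#' bottom of the scale) is taken.
#'
#' @param table categorical data.frame of ordered factors.
#' @return named character vector of median category labels.
#' @export
median_categories <- function(table) {
  out <- character(0)
  for (f in names(table)) {
    x <- table[[f]]
    if (!is.factor(x)) next
    r <- sort(as.integer(x[!is.na(x)]))
    if (length(r) == 0) next
    med <- r[ceiling(length(r) / 2)]
    out[f] <- levels(x)[med]
  }
  out
}

# Posterior marginals of the missing variables in one row by exact
# enumeration over their joint category grid, conditioning on every
# observed variable (or, with parents_only, scoring only each node's family).
.row_posteriors <- function(row, bn, missing_vars) {
  grids <- lapply(missing_vars, function(n) bn$cpts[[n]]$levels)
  names(grids) <- missing_vars
  grid <- expand.grid(grids, stringsAsFactors = FALSE)
  ng <- nrow(grid)
  assign_df <- grid
  for (n in setdiff(bn$order, missing_vars))
    assign_df[[n]] <- rep(as.character(row[[n]]), ng)
  logp <- numeric(ng)
  for (n in bn$order) {
    cpt <- bn$cpts[[n]]
    ci <- .config_index(cpt, assign_df)
    vi <- match(assign_df[[n]], cpt$levels)
    logp <- logp + log(cpt$prob[cbind(ci, vi)])
  }
  w <- exp(logp - max(logp))
  w <- w / sum(w)
  lapply(stats::setNames(missing_vars, missing_vars), function(n) {
    tapply(w, factor(grid[[n]], levels = bn$cpts[[n]]$levels), sum,
           default = 0)
  })
}

# Argmax with the clinical tie policy: prefer the median category when tied;
# otherwise the tied category ordinally closest to the median; equal
# distances resolve to the lower ordinal.
.argmax_with_ties <- function(post, levels_, median_label, tol = 1e-9) {
  post <- as.numeric(post)
  top <- max(post)
  tied <- which(post >= top - tol)
  if (length(tied) == 1) return(levels_[tied])
  med_rank <- match(median_label, levels_)
  if (is.na(med_rank)) med_rank <- ceiling(length(levels_) / 2)
  if (med_rank %in% tied) return(levels_[med_rank])
  d <- abs(tied - med_rank)
  cand <- tied[d == min(d)]
  levels_[min(cand)]
}

#' Impute missing categories by Bayesian inference
#'
#' Fills each missing cell with the maximum-posterior category given the
#' row's observed variables, by exact enumeration on the network (9 nodes,
#' at most 3 categories each in the default scheme, so enumeration is
#' trivial). Ties are broken by (1) the training-set median category if it
#' is among the tied set, (2) else the tied category ordinally closest to
#' the median (the less extreme value), (3) else the lower ordinal. Rows
#' must observe all root features — filter with [filter_root_complete()]
#' first. Observed cells are never altered.
#'
#' @param table categorical data.frame (ordered factors; outcome 0/1 or
#'   absent; outcome missing cells are also imputed if present and `NA`).
#' @param bn a [fitted_bayesnet()].
#' @param train_medians named character vector of median categories from
#'   [median_categories()] on the training table.
#' @param parents_only if `TRUE`, condition each node only on its parents
#'   (the literal guideline reading) instead of on all observed variables.
#' @return `table` with missing cells filled.
#' @export
bn_impute <- function(table, bn, train_medians, parents_only = FALSE) {
  nodes <- intersect(bn$structure$nodes, names(table))
  absent <- setdiff(bn$structure$nodes, names(table))  # marginalised over
  roots <- structure_roots(bn$structure)
  out <- table
  char <- lapply(stats::setNames(nodes, nodes),
                 function(n) as.character(table[[n]]))
  cache <- new.env(parent = emptyenv())  # rows with equal signatures impute equally
  sig <- do.call(paste, c(char, sep = "\r"))
  for (i in seq_len(nrow(table))) {
    miss <- nodes[vapply(nodes, function(n) is.na(char[[n]][i]), logical(1))]
    if (length(miss) == 0) next
    hit <- cache[[sig[i]]]
    if (!is.null(hit)) {
      for (n in miss) {
        if (is.factor(out[[n]])) {
          out[[n]][i] <- factor(hit[[n]], levels = levels(out[[n]]),
                                ordered = is.ordered(out[[n]]))
        } else out[[n]][i] <- hit[[n]]
      }
      next
    }
    bad_roots <- intersect(miss, roots)
    if (length(bad_roots))
      stop("row ", i, " is missing root feature(s): ",
           paste(bad_roots, collapse = ", "),
           "; apply filter_root_complete() first")
    row <- lapply(char, `[`, i)
    if (parents_only) {
      # impute in topological order from parent values alone
      for (n in bn$order) {
        if (!n %in% miss) next
        cpt <- bn$cpts[[n]]
        if (length(setdiff(cpt$parents, names(row))))
          stop("parents_only imputation of ", n,
               " needs parent column(s) absent from the table")
        pv <- as.data.frame(row[cpt$parents], stringsAsFactors = FALSE)
        if (length(cpt$parents) == 0) pv <- data.frame(row.names = 1)
        post <- cpt$prob[.config_index(cpt, pv), ]
        row[[n]] <- .argmax_with_ties(post, cpt$levels, train_medians[n])
      }
    } else {
      post <- .row_posteriors(row, bn, c(miss, absent))
      for (n in miss)
        row[[n]] <- .argmax_with_ties(post[[n]], bn$cpts[[n]]$levels,
                                      train_medians[n])
    }
    for (n in miss) {
      if (is.factor(out[[n]])) {
        out[[n]][i] <- factor(row[[n]], levels = levels(out[[n]]),
                              ordered = is.ordered(out[[n]]))
      } else {
        out[[n]][i] <- row[[n]]
      }
    }
    cache[[sig[i]]] <- row[miss]
  }
  out
}

#' Serialise a fitted network to JSON
#'
#' @param bn a [fitted_bayesnet()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bayesnet <- function(bn, path) {
  x <- list(
    nodes = bn$structure$nodes,
    outcome = bn$structure$outcome,
    edges = lapply(seq_len(nrow(bn$structure$edges)), function(i)
      list(from = bn$structure$edges$from[i], to = bn$structure$edges$to[i])),
    cpts = lapply(bn$cpts, function(c)
      list(parents = c$parents, levels = c$levels,
           parent_levels = c$parent_levels,
           prob = unname(apply(c$prob, 1, as.numeric, simplify = FALSE))))
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a fitted network from JSON
#'
#' @param path input path.
#' @return a [fitted_bayesnet()].
#' @export
read_bayesnet <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  edges <- do.call(rbind, lapply(x$edges, function(e) c(e$from, e$to)))
  structure <- causal_structure(unlist(x$nodes), edges, outcome = x$outcome)
  cpts <- lapply(x$cpts, function(c) {
    prob <- do.call(rbind, lapply(c$prob, function(r) vapply(r, as.numeric, numeric(1))))
    list(parents = as.character(unlist(c$parents)),
         levels = as.character(unlist(c$levels)),
         parent_levels = lapply(c$parent_levels, function(l) as.character(unlist(l))),
         prob = prob)
  })
  fitted_bayesnet(structure, cpts)
}
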