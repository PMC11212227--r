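#' Threshold literal
#'
#' One comparison of a feature against a clinical threshold, e.g.
#' `BMI >= 30`. Conjunctions of literals form guideline rules.
#'
#' @param feature feature name (aliases accepted).
#' @param op one of `"<="`, `">="`, `"<"`, `">"`.
#' @param threshold finite numeric threshold in the feature's units.
#' @return An object of class `threshold_literal`.
#' @export
threshold_literal <- function(feature, op, threshold) {
  op <- match.arg(op, c("<=", ">=", "<", ">"))
  if (!is.numeric(threshold) || length(threshold) != 1 || !is.finite(threshold))
    stop("threshold must be a single finite number")
  structure(
    list(feature = canonical_features(feature), op = op,
         threshold = as.numeric(threshold)),
    class = "threshold_literal"
  )
}

literal_holds <- function(lit, value) {
  if (is.na(value)) return(NA)
  switch(lit$op,
    "<=" = value <= lit$threshold,
    ">=" = value >= lit$threshold,
    "<"  = value <  lit$threshold,
    ">"  = value >  lit$threshold
  )
}

#' Guideline logic rule
#'
#' A conjunction of threshold literals implying a class label. A record
#' satisfies the rule iff every literal holds; thresholds are inclusive or
#' strict exactly as written in the operator.
#'
#' @param literals list of [threshold_literal()] objects (at least one).
#' @param consequent `"diabetes"` (positive class) or `"healthy"`.
#' @return An object of class `logic_rule`.
#' @export
logic_rule <- function(literals, consequent = c("diabetes", "healthy")) {
  consequent <- match.arg(consequent)
  if (length(literals) < 1) stop("a rule needs at least one literal")
  stopifnot(all(vapply(literals, inherits, logical(1), "threshold_literal")))
  structure(list(literals = literals, consequent = consequent),
            class = "logic_rule")
}

rule_satisfied <- function(rule, record) {
  for (lit in rule$literals) {
    v <- record[[lit$feature]]
    if (is.null(v)) v <- NA_real_
    h <- literal_holds(lit, v)
    if (is.na(h) || !h) return(FALSE)
  }
  TRUE
}

#' Tri-state rule verdict for a single record
#'
#' Evaluates the rule set on one record. Returns `"positive"` if any rule
#' with a diabetes consequent is satisfied, `"negative"` if any rule with a
#' healthy consequent is satisfied, `"abstain"` otherwise. A record missing
#' a referenced feature never satisfies the rule (the rule abstains for it);
#' a warning is emitted since rules are meant to run on imputed data.
#'
#' @param record named list / vector / one-row data.frame of feature values.
#' @param rules list of [logic_rule()] objects.
#' @return `"positive"`, `"negative"` or `"abstain"`.
#' @export
rule_decision <- function(record, rules) {
  if (is.data.frame(record)) record <- as.list(record[1, , drop = FALSE])
  record <- as.list(record)
  names(record) <- canonical_features(names(record))
  referenced <- unique(unlist(lapply(rules, function(r)
    vapply(r$literals, function(l) l$feature, character(1)))))
  miss <- referenced[vapply(referenced, function(f)
    is.null(record[[f]]) || is.na(record[[f]]), logical(1))]
  if (length(miss) > 0)
    warning("record is missing referenced feature(s): ",
            paste(miss, collapse = ", "), "; rules over them abstain")
  verdict <- "abstain"
  for (rule in rules) {
    if (rule_satisfied(rule, record)) {
      v <- if (rule$consequent == "diabetes") "positive" else "negative"
      if (verdict != "abstain" && verdict != v)
        stop("conflicting rules both satisfied; knowledge base is inconsistent")
      verdict <- v
    }
  }
  verdict
}

#' Discretisation scheme
#'
#' Per-feature ordered intervals mapping numeric measurements to ordinal
#' clinical categories (e.g. Low < Medium < High). Intervals are stored with
#' explicit closure flags because published boundaries mix conventions
#' (glucose >= 126 is inclusive, blood pressure < 80 is strict).
#'
#' @param intervals named list; each element is a data.frame with columns
#'   `label`, `lower`, `upper`, `lower_closed`, `upper_closed`, rows ordered
#'   from lowest to highest interval. Labels are ordinal, rank = row order.
#' @return An object of class `discretisation_scheme`.
#' @export
discretisation_scheme <- function(intervals) {
  stopifnot(is.list(intervals), length(intervals) >= 1, !is.null(names(intervals)))
  names(intervals) <- canonical_features(names(intervals))
  for (f in names(intervals)) {
    d <- intervals[[f]]
    need <- c("label", "lower", "upper", "lower_closed", "upper_closed")
    if (!all(need %in% names(d)))
      stop("intervals for ", f, " must have columns ",
           paste(need, collapse = ", "))
    intervals[[f]] <- d[, need]
  }
  structure(list(intervals = intervals), class = "discretisation_scheme")
}

scheme_levels <- function(scheme, feature) {
  as.character(scheme$intervals[[feature]]$label)
}

scheme_features <- function(scheme) names(scheme$intervals)

# TRUE where x lies in interval row `iv` (vectorised over x).
.in_interval <- function(x, iv) {
  lo <- if (iv$lower_closed) x >= iv$lower else x > iv$lower
  hi <- if (iv$upper_closed) x <= iv$upper else x < iv$upper
  lo & hi
}

# Plausible range of a feature = hull of its intervals.
scheme_range <- function(scheme, feature) {
  d <- scheme$intervals[[feature]]
  list(lower = d$lower[1], lower_closed = d$lower_closed[1],
       upper = d$upper[nrow(d)], upper_closed = d$upper_closed[nrow(d)])
}

#' Causal structure
#'
#' A directed acyclic graph over the schema features plus one outcome node,
#' encoding which features cause or are caused by the outcome and each other.
#'
#' @param nodes character vector of node names (features + outcome).
#' @param edges two-column matrix or data.frame of directed `from -> to` pairs.
#' @param outcome name of the outcome node.
#' @return An object of class `causal_structure`.
#' @export
causal_structure <- function(nodes, edges, outcome = "Outcome") {
  edges <- as.data.frame(edges)
  names(edges) <- c("from", "to")
  edges$from <- canonical_features(as.character(edges$from))
  edges$to <- canonical_features(as.character(edges$to))
  nodes <- canonical_features(nodes)
  if (!outcome %in% nodes) stop("outcome node must be present")
  bad <- setdiff(unique(c(edges$from, edges$to)), nodes)
  if (length(bad)) stop("edges reference unknown nodes: ", paste(bad, collapse = ", "))
  structure(list(nodes = nodes, edges = edges, outcome = outcome),
            class = "causal_structure")
}

structure_parents <- function(structure, node) {
  structure$edges$from[structure$edges$to == node]
}

structure_children <- function(structure, node) {
  structure$edges$to[structure$edges$from == node]
}

#' Root features of a causal structure
#'
#' Features with no parents in the DAG (the outcome node is excluded even if
#' parentless).
#' @param structure a [causal_structure()].
#' @return character vector of root feature names.
#' @export
structure_roots <- function(structure) {
  feats <- setdiff(structure$nodes, structure$outcome)
  feats[vapply(feats, function(n) length(structure_parents(structure, n)) == 0,
               logical(1))]
}

# Kahn topological sort; NULL if the graph has a cycle.
topological_order <- function(structure) {
  nodes <- structure$nodes
  indeg <- vapply(nodes, function(n) sum(structure$edges$to == n), integer(1))
  order <- character(0)
  avail <- nodes[indeg == 0]
  indeg <- stats::setNames(indeg, nodes)
  while (length(avail) > 0) {
    n <- avail[1]; avail <- avail[-1]
    order <- c(order, n)
    for (ch in structure_children(structure, n)) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0) avail <- c(avail, ch)
    }
  }
  if (length(order) != length(nodes)) NULL else order
}

#' Composite clinical index formula
#'
#' A linear formula `intercept + sum(coefficient * feature)` defining a
#' derived clinical index such as an insulin-sensitivity estimate.
#'
#' @param name identifier for the derived column.
#' @param intercept numeric intercept.
#' @param coefficients named numeric vector, names are feature names.
#' @return An object of class `composite_formula`.
#' @export
composite_formula <- function(name, intercept, coefficients) {
  stopifnot(is.character(name), is.numeric(intercept), is.numeric(coefficients),
            !is.null(names(coefficients)))
  names(coefficients) <- canonical_features(names(coefficients))
  structure(list(name = name, intercept = as.numeric(intercept),
                 coefficients = coefficients),
            class = "composite_formula")
}

#' The demographic Stumvoll insulin-sensitivity index
#'
#' Estimates insulin sensitivity from BMI, the 2-hour OGTT insulin level and
#' age: `0.222 - 0.00333*BMI - 0.0000779*I120 - 0.000422*Age`.
#'
#' @return A [composite_formula()] named `"Stumvoll"`.
#' @export
stumvoll_formula <- function() {
  composite_formula(
    "Stumvoll", intercept = 0.222,
    coefficients = c(BMI = -0.00333, I120 = -0.0000779, Age = -0.000422)
  )
}

#' Knowledge base
#'
#' Bundle of the four declarative knowledge components over one shared
#' feature schema: a discretisation scheme, guideline logic rules, a causal
#' DAG, composite-index formulas, and the set of features whose zero values
#' are physiologically implausible and must be treated as missing.
#'
#' @param scheme a [discretisation_scheme()].
#' @param rules list of [logic_rule()]s.
#' @param structure a [causal_structure()].
#' @param formulas list of [composite_formula()]s.
#' @param implausible_zero_features character vector of feature names.
#' @param schema a [feature_schema()].
#' @return An object of class `knowledge_base`.
#' @export
knowledge_base <- function(scheme, rules, structure, formulas,
                           implausible_zero_features,
                           schema = pima_schema()) {
  out <- list(scheme = scheme, rules = rules, structure = structure,
              formulas = formulas,
              implausible_zero_features = canonical_features(implausible_zero_features),
              schema = schema)
  class(out) <- "knowledge_base"
  out
}

.iv <- function(label, lower, upper, lower_closed, upper_closed) {
  data.frame(label = label, lower = lower, upper = upper,
             lower_closed = lower_closed, upper_closed = upper_closed,
             stringsAsFactors = FALSE)
}

#' Default type-2 diabetes discretisation scheme
#'
#' Three ordinal categories per feature. Glucose (100 / 126) and BMI
#' (25 / 30) boundaries follow the guideline rule thresholds; blood pressure
#' uses the hypertension stages (< 80 / 80-89 / >= 90 mmHg); 2-hour insulin
#' uses the 16-166 uU/ml reference range; triceps skin-fold 10-40 mm; DPF
#' cut at 0.4 / 0.8; age groups at 30 / 45 years; pregnancies at 1 / 5.
#' Boundaries without a published textual source are provisional defaults,
#' overridable by constructing a custom scheme.
#'
#' @return A [discretisation_scheme()] over the Pima features.
#' @export
default_pima_scheme <- function() {
  discretisation_scheme(list(
    G120 = rbind(
      .iv("Low",    0,   100, TRUE,  TRUE),
      .iv("Medium", 100, 126, FALSE, FALSE),
      .iv("High",   126, Inf, TRUE,  FALSE)
    ),
    BMI = rbind(
      .iv("Normal", 0,  25,  TRUE,  TRUE),
      .iv("Medium", 25, 30,  FALSE, FALSE),
      .iv("High",   30, Inf, TRUE,  FALSE)
    ),
    BP = rbind(
      .iv("Low",    0,  80,  TRUE,  FALSE),
      .iv("Medium", 80, 90,  TRUE,  FALSE),
      .iv("High",   90, Inf, TRUE,  FALSE)
    ),
    I120 = rbind(
      .iv("Low",    0,   16,  TRUE,  FALSE),
      .iv("Medium", 16,  166, TRUE,  TRUE),
      .iv("High",   166, Inf, FALSE, FALSE)
    ),
    ST = rbind(
      .iv("Low",    0,  10,  TRUE,  FALSE),
      .iv("Medium", 10, 40,  TRUE,  TRUE),
      .iv("High",   40, Inf, FALSE, FALSE)
    ),
    DPF = rbind(
      .iv("Low",    0,   0.4, TRUE,  FALSE),
      .iv("Medium", 0.4, 0.8, TRUE,  FALSE),
      .iv("High",   0.8, Inf, TRUE,  FALSE)
    ),
    Age = rbind(
      .iv("Young",  21, 30,  TRUE,  FALSE),
      .iv("Middle", 30, 45,  TRUE,  FALSE),
      .iv("Senior", 45, Inf, TRUE,  FALSE)
    ),
    Pregnancies = rbind(
      .iv("Low",    0, 1,   TRUE,  TRUE),
      .iv("Medium", 1, 5,   FALSE, TRUE),
      .iv("High",   5, Inf, FALSE, FALSE)
    )
  ))
}

#' Default causal DAG for the diabetes case study
#'
#' Roots are the acknowledged potential causes of diabetes (pregnancies,
#' age, BMI, family history); the 2-hour glucose and insulin tests are
#' direct indicators (children of the outcome); skin thickness reflects
#' obesity only; blood pressure is caused by both obesity and diabetes.
#'
#' @return A [causal_structure()] over the 8 features + Outcome.
#' @export
default_pima_structure <- function() {
  causal_structure(
    nodes = c(pima_schema()$features, "Outcome"),
    edges = rbind(
      c("Age", "Outcome"), c("DPF", "Outcome"),
      c("Pregnancies", "Outcome"), c("BMI", "Outcome"),
      c("BMI", "ST"), c("BMI", "BP"),
      c("Outcome", "G120"), c("Outcome", "I120"), c("Outcome", "BP")
    )
  )
}

#' The default type-2 diabetes knowledge base
#'
#' The shipped case-study knowledge base: the two public-health guideline
#' rules (`BMI >= 30 & G120 >= 126 => diabetes`;
#' `BMI <= 25 & G120 <= 100 => healthy`), the causal DAG
#' ([default_pima_structure()]), the demographic Stumvoll formula, the
#' default interval scheme, and the implausible-zero feature set
#' {G120, BP, ST, I120, BMI}.
#'
#' @return A [knowledge_base()].
#' @export
default_pima_knowledge <- function() {
  rules <- list(
    logic_rule(list(threshold_literal("BMI", ">=", 30),
                    threshold_literal("G120", ">=", 126)),
               consequent = "diabetes"),
    logic_rule(list(threshold_literal("BMI", "<=", 25),
                    threshold_literal("G120", "<=", 100)),
               consequent = "healthy")
  )
  knowledge_base(
    scheme = default_pima_scheme(),
    rules = rules,
    structure = default_pima_structure(),
    formulas = list(stumvoll_formula()),
    implausible_zero_features = c("G120", "BP", "ST", "I120", "BMI")
  )
}

# Interval of values of `feature` satisfying all `literals` on it, as
# list(lower, upper, lower_closed, upper_closed); NULL if empty.
.literal_intersection <- function(literals) {
  lower <- -Inf; upper <- Inf; lc <- FALSE; uc <- FALSE
  for (lit in literals) {
    if (lit$op %in% c(">=", ">")) {
      closed <- lit$op == ">="
      if (lit$threshold > lower || (lit$threshold == lower && lc && !closed)) {
        lower <- lit$threshold; lc <- closed
      }
    } else {
      closed <- lit$op == "<="
      if (lit$threshold < upper || (lit$threshold == upper && uc && !closed)) {
        upper <- lit$threshold; uc <- closed
      }
    }
  }
  if (lower > upper) return(NULL)
  if (lower == upper && !(lc && uc)) return(NULL)
  list(lower = lower, upper = upper, lower_closed = lc, upper_closed = uc)
}

# TRUE iff the conjunction of the two rules' antecedents is satisfiable.
.antecedents_intersect <- function(rule_a, rule_b) {
  lits <- c(rule_a$literals, rule_b$literals)
  feats <- unique(vapply(lits, function(l) l$feature, character(1)))
  for (f in feats) {
    sub <- Filter(function(l) l$feature == f, lits)
    if (is.null(.literal_intersection(sub))) return(FALSE)
  }
  TRUE
}

#' Validate a knowledge base
#'
#' Checks structural consistency and returns violations instead of raising:
#' the DAG must be acyclic; each feature's intervals must be ordered,
#' non-overlapping and gap-free (adjacent bounds meet with exactly one side
#' closed); rules with conflicting consequents must have unsatisfiable joint
#' antecedents; formula features must exist in the schema.
#'
#' @param kb a [knowledge_base()].
#' @return character vector of violation messages; empty if valid.
#' @export
validate_knowledge <- function(kb) {
  v <- character(0)
  if (is.null(topological_order(kb$structure)))
    v <- c(v, "causal structure contains a cycle")
  known <- c(kb$schema$features, kb$schema$outcome)
  bad_nodes <- setdiff(kb$structure$nodes, known)
  if (length(bad_nodes))
    v <- c(v, paste0("structure nodes not in schema: ",
                     paste(bad_nodes, collapse = ", ")))
  for (f in scheme_features(kb$scheme)) {
    d <- kb$scheme$intervals[[f]]
    if (nrow(d) == 0) { v <- c(v, paste0(f, ": empty interval list")); next }
    if (any(d$lower >= d$upper))
      v <- c(v, paste0(f, ": interval with lower >= upper"))
    if (nrow(d) > 1) {
      for (i in seq_len(nrow(d) - 1)) {
        if (d$upper[i] != d$lower[i + 1])
          v <- c(v, paste0(f, ": gap or overlap between intervals ", i,
                           " and ", i + 1))
        else if (d$upper_closed[i] == d$lower_closed[i + 1])
          v <- c(v, paste0(f, ": boundary ", d$upper[i],
                           " covered twice or not at all"))
      }
    }
    if (!f %in% kb$schema$features)
      v <- c(v, paste0("scheme feature not in schema: ", f))
  }
  nr <- length(kb$rules)
  if (nr > 1) {
    for (i in seq_len(nr - 1)) for (j in seq((i + 1), nr)) {
      ri <- kb$rules[[i]]; rj <- kb$rules[[j]]
      if (ri$consequent != rj$consequent &&
          .antecedents_intersect(ri, rj))
        v <- c(v, paste0("rules ", i, " and ", j,
                         " have conflicting consequents but overlapping antecedents"))
    }
  }
  for (fm in kb$formulas) {
    bad <- setdiff(names(fm$coefficients), kb$schema$features)
    if (length(bad))
      v <- c(v, paste0("formula ", fm$name, " references unknown feature(s): ",
                       paste(bad, collapse = ", ")))
  }
  v
}

#' @export
print.knowledge_base <- function(x, ...) {
  cat("Knowledge base:\n")
  cat(" ", length(x$rules), "rules;", nrow(x$structure$edges),
      "causal edges;", length(x$formulas), "formulas\n")
  cat("  discretised features:",
      paste(scheme_features(x$scheme), collapse = ", "), "\n")
  cat("  implausible-zero features:",
      paste(x$implausible_zero_features, collapse = ", "), "\n")
  invisible(x)
}
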