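#' Case-study missingness rates
#'
#' Per-feature missing fractions observed in the real cohort (2-hour
#' insulin 48.70%, skin thickness 29.56%, blood pressure 4.55%, BMI 1.43%,
#' glucose 0.65%), used as the default rates for synthetic masking.
#'
#' @return named numeric vector of missing probabilities.
#' @export
pima_missing_rates <- function() {
  c(I120 = 0.4870, ST = 0.2956, BP = 0.0455, BMI = 0.0143, G120 = 0.0065)
}

# Linear interpolation between two distributions; stays a distribution.
.mix <- function(d0, d1, s) (1 - s) * d0 + s * d1

#' Default synthetic cohort generator network
#'
#' A fitted Bayesian network over the default causal DAG with hand-set
#' CPTs emulating a high-risk adult cohort: root marginals skewed toward
#' elevated BMI, an outcome probability logistic in the ordinal ranks of
#' the four root causes, glucose strongly and insulin moderately shifted by
#' the outcome, skin thickness driven by BMI only, and blood pressure
#' raised by both BMI and the outcome. These are package fixtures chosen so
#' that outcome prevalence and guideline-rule coverage sit near one third
#' of samples; they are not estimates from any real data.
#'
#' @param kb a [knowledge_base()] supplying the structure and category sets.
#' @return a [fitted_bayesnet()].
#' @export
default_generator_bn <- function(kb = default_pima_knowledge()) {
  structure <- kb$structure
  scheme <- kb$scheme
  levs <- .node_levels(structure, scheme)
  cpt <- function(node, prob) {
    parents <- structure_parents(structure, node)
    list(parents = parents, levels = levs[[node]],
         parent_levels = levs[parents], prob = prob)
  }
  root_probs <- list(
    Pregnancies = c(0.35, 0.40, 0.25),
    Age = c(0.45, 0.35, 0.20),
    BMI = c(0.25, 0.25, 0.50),
    DPF = c(0.50, 0.30, 0.20)
  )
  cpts <- list()
  for (f in names(root_probs))
    cpts[[f]] <- cpt(f, matrix(root_probs[[f]], nrow = 1))
  # Outcome | Age, DPF, Pregnancies, BMI — logistic in ordinal ranks 1..3
  op <- structure_parents(structure, "Outcome")
  grid <- expand.grid(lapply(levs[op], seq_along))
  names(grid) <- op
  beta <- c(Age = 0.55, DPF = 0.60, Pregnancies = 0.45, BMI = 0.95)
  eta <- -3.2 + rowSums(sapply(op, function(p) beta[[p]] * (grid[[p]] - 1)))
  p1 <- 1 / (1 + exp(-eta))
  cpts$Outcome <- cpt("Outcome", cbind(1 - p1, p1))
  cpts$G120 <- cpt("G120", rbind(
    c(0.58, 0.34, 0.08),   # Outcome = 0
    c(0.07, 0.35, 0.58)    # Outcome = 1
  ))
  cpts$I120 <- cpt("I120", rbind(
    c(0.40, 0.50, 0.10),
    c(0.15, 0.50, 0.35)
  ))
  cpts$ST <- cpt("ST", rbind(
    c(0.50, 0.42, 0.08),   # BMI = Normal
    c(0.20, 0.55, 0.25),   # BMI = Medium
    c(0.08, 0.42, 0.50)    # BMI = High
  ))
  # BP | BMI, Outcome — interpolate between a normotensive and a
  # hypertensive profile as BMI rank and outcome rise
  bp_grid <- expand.grid(BMI = 1:3, Outcome = 0:1)
  d0 <- c(0.55, 0.30, 0.15); d1 <- c(0.15, 0.35, 0.50)
  bp <- t(apply(bp_grid, 1, function(g)
    .mix(d0, d1, 0.6 * (g[["BMI"]] - 1) / 2 + 0.4 * g[["Outcome"]])))
  cpts$BP <- cpt("BP", bp)
  fitted_bayesnet(structure, cpts)
}

#' Default per-category numeric sampling ranges
#'
#' For each feature and category, the numeric interval that synthetic
#' values are drawn from (uniformly). Every range lies strictly within the
#' corresponding discretisation interval, so generated values always
#' re-discretise to their latent category. `Pregnancies` and `Age` are
#' drawn as integers.
#'
#' @return named list; per feature a data.frame with columns `label`,
#'   `lo`, `hi`, `integer`.
#' @export
default_numeric_ranges <- function() {
  rng <- function(labels, lo, hi, integer = FALSE)
    data.frame(label = labels, lo = lo, hi = hi, integer = integer,
               stringsAsFactors = FALSE)
  list(
    G120 = rng(c("Low", "Medium", "High"), c(70, 100.5, 126), c(100, 125.5, 199)),
    BMI = rng(c("Normal", "Medium", "High"), c(16, 25.1, 30), c(25, 29.9, 49)),
    BP = rng(c("Low", "Medium", "High"), c(40, 80, 90), c(79.5, 89.5, 120)),
    I120 = rng(c("Low", "Medium", "High"), c(5, 16, 166.5), c(15.5, 166, 400)),
    ST = rng(c("Low", "Medium", "High"), c(3, 10, 40.5), c(9.5, 40, 70)),
    DPF = rng(c("Low", "Medium", "High"), c(0.05, 0.4, 0.8), c(0.39, 0.79, 1.8)),
    Age = rng(c("Young", "Middle", "Senior"), c(21, 30, 45), c(29, 44, 70),
              integer = TRUE),
    Pregnancies = rng(c("Low", "Medium", "High"), c(0, 2, 6), c(1, 5, 12),
                      integer = TRUE)
  )
}

#' Synthetic cohort configuration
#'
#' @param n number of records (>= 1).
#' @param bn generator network (a [fitted_bayesnet()]).
#' @param ranges per-category numeric ranges ([default_numeric_ranges()]).
#' @param missing_rates optional named per-feature missing probabilities
#'   applied after sampling (`NULL` = no masking).
#' @param seed RNG seed.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n, bn = default_generator_bn(),
                             ranges = default_numeric_ranges(),
                             missing_rates = NULL, seed = 1) {
  if (n < 1) stop("n must be >= 1")
  if (!is.null(missing_rates) &&
      any(missing_rates < 0 | missing_rates > 1))
    stop("missing rates must be in [0, 1]")
  for (f in names(ranges)) {
    if (any(ranges[[f]]$lo > ranges[[f]]$hi))
      stop("invalid numeric range for ", f)
  }
  out <- list(n = as.integer(n), bn = bn, ranges = ranges,
              missing_rates = missing_rates, seed = seed)
  class(out) <- "synthetic_config"
  out
}

# Vectorised ancestral sampling of categories; `clamp` optionally restricts
# nodes to a category subset (renormalised) or forces the outcome value.
.sample_categories <- function(bn, n, clamp = list()) {
  draws <- list()
  for (node in bn$order) {
    cpt <- bn$cpts[[node]]
    idx <- if (length(cpt$parents) == 0) rep(1L, n)
           else .config_index(cpt, as.data.frame(draws[cpt$parents],
                                                 stringsAsFactors = FALSE))
    prob <- cpt$prob[idx, , drop = FALSE]
    if (!is.null(clamp[[node]])) {
      keep <- cpt$levels %in% clamp[[node]]
      if (!any(keep)) stop("clamp on ", node, " excludes every category")
      prob[, !keep] <- 0
      rs <- rowSums(prob)
      if (any(rs == 0))
        # a parent configuration gives the clamped set zero mass; fall back
        # to uniform over the allowed categories
        prob[rs == 0, keep] <- 1
      prob <- prob / rowSums(prob)
    }
    cum <- prob
    for (j in seq_len(ncol(cum))[-1]) cum[, j] <- cum[, j] + cum[, j - 1]
    u <- stats::runif(n)
    ci <- rowSums(u > cum) + 1L
    draws[[node]] <- cpt$levels[ci]
  }
  draws
}

#' Sample a synthetic cohort
#'
#' Ancestral (topological-order) sampling of ordinal categories from the
#' generator network, followed by a uniform numeric draw within each
#' category's configured range. The outcome label is the network's outcome
#' node. Fully reproducible under the config seed.
#'
#' @param config a [synthetic_config()].
#' @return a list with `numeric` (cohort data.frame with outcome column;
#'   missingness injected if the config carries rates) and `categories`
#'   (the latent categorical table as ordered factors, never masked).
#' @export
sample_cohort <- function(config) {
  set.seed(config$seed)
  n <- config$n
  bn <- config$bn
  draws <- .sample_categories(bn, n)
  outcome <- bn$structure$outcome
  feats <- setdiff(bn$structure$nodes, outcome)
  numeric_tab <- list()
  for (f in feats) {
    rg <- config$ranges[[f]]
    if (is.null(rg)) stop("no numeric ranges configured for ", f)
    pos <- match(draws[[f]], rg$label)
    lo <- rg$lo[pos]; hi <- rg$hi[pos]
    x <- if (all(rg$integer)) {
      floor(stats::runif(n, lo, hi + 1 - 1e-9))
    } else {
      stats::runif(n, lo, hi)
    }
    numeric_tab[[f]] <- x
  }
  numeric_tab[[outcome]] <- as.integer(draws[[outcome]])
  numeric_df <- as.data.frame(numeric_tab)
  cat_df <- as.data.frame(
    lapply(stats::setNames(feats, feats), function(f)
      factor(draws[[f]], levels = bn$cpts[[f]]$levels, ordered = TRUE)))
  cat_df[[outcome]] <- numeric_df[[outcome]]
  if (!is.null(config$missing_rates)) {
    numeric_df <- inject_missingness(numeric_df, config$missing_rates,
                                     seed = config$seed + 1L)
  }
  list(numeric = numeric_df, categories = cat_df)
}

#' Exact outcome prevalence implied by a generator network
#'
#' Enumerates the root configurations and sums
#' `P(roots) * P(outcome = 1 | roots)`.
#'
#' @param bn a [fitted_bayesnet()].
#' @return probability of a positive outcome.
#' @export
implied_prevalence <- function(bn) {
  outcome <- bn$structure$outcome
  cpt <- bn$cpts[[outcome]]
  roots <- cpt$parents
  grid <- expand.grid(cpt$parent_levels, stringsAsFactors = FALSE)
  pr <- rep(1, nrow(grid))
  for (r in roots) {
    rp <- bn$cpts[[r]]$prob[1, ]
    pr <- pr * rp[match(grid[[r]], bn$cpts[[r]]$levels)]
  }
  idx <- .config_index(cpt, grid)
  pos_col <- match("1", cpt$levels)
  sum(pr * cpt$prob[idx, pos_col])
}

#' Exact guideline-rule coverage implied by the default generator
#'
#' Probability that a sampled record satisfies either guideline rule, i.e.
#' lands in (BMI High, G120 High) or (BMI lowest, G120 Low), computed by
#' enumerating roots and outcome.
#'
#' @param bn a [fitted_bayesnet()].
#' @return probability that one of the two rules fires.
#' @export
implied_rule_coverage <- function(bn) {
  outcome <- bn$structure$outcome
  ocpt <- bn$cpts[[outcome]]
  grid <- expand.grid(ocpt$parent_levels, stringsAsFactors = FALSE)
  pr <- rep(1, nrow(grid))
  for (r in ocpt$parents) {
    rp <- bn$cpts[[r]]$prob[1, ]
    pr <- pr * rp[match(grid[[r]], bn$cpts[[r]]$levels)]
  }
  p1 <- ocpt$prob[.config_index(ocpt, grid), match("1", ocpt$levels)]
  g <- bn$cpts$G120
  g_high <- g$prob[, match("High", g$levels)]    # indexed by outcome 0/1
  g_low <- g$prob[, match("Low", g$levels)]
  bmi_levels <- bn$cpts$BMI$levels
  high_bmi <- grid$BMI == bmi_levels[length(bmi_levels)]
  low_bmi <- grid$BMI == bmi_levels[1]
  rule1 <- sum(pr[high_bmi] * ((1 - p1[high_bmi]) * g_high[1] +
                               p1[high_bmi] * g_high[2]))
  rule2 <- sum(pr[low_bmi] * ((1 - p1[low_bmi]) * g_low[1] +
                              p1[low_bmi] * g_low[2]))
  rule1 + rule2
}

#' Inject missing values
#'
#' Masks each cell of feature `f` independently with probability
#' `rates[f]` (missing completely at random). With `mechanism = "MAR"` the
#' masking probability depends on the outcome (rate scaled by
#' `2 * mar_weight` for positive outcomes and `2 * (1 - mar_weight)` for
#' negative ones, preserving the marginal rate at 50% prevalence) — a
#' stress-test mode for comparing imputation methods. Outcome labels are
#' never masked.
#'
#' @param table cohort data.frame.
#' @param rates named per-feature missing probabilities.
#' @param seed RNG seed.
#' @param mechanism `"MCAR"` (default) or `"MAR"`.
#' @param mar_weight share of the masking mass on positive-outcome rows
#'   (MAR mode only).
#' @param outcome outcome column name.
#' @return the table with masked cells set to `NA`.
#' @export
inject_missingness <- function(table, rates = pima_missing_rates(),
                               seed = 1, mechanism = c("MCAR", "MAR"),
                               mar_weight = 0.7, outcome = "Outcome") {
  mechanism <- match.arg(mechanism)
  unknown <- setdiff(names(rates), names(table))
  if (length(unknown))
    stop("rates given for unknown feature(s): ",
         paste(unknown, collapse = ", "))
  if (any(rates < 0 | rates > 1)) stop("rates must be in [0, 1]")
  set.seed(seed)
  out <- table
  n <- nrow(table)
  for (f in names(rates)) {
    p <- rep(rates[[f]], n)
    if (mechanism == "MAR" && outcome %in% names(table)) {
      y <- table[[outcome]]
      p <- ifelse(y == 1, 2 * mar_weight, 2 * (1 - mar_weight)) * p
      p <- pmin(1, p)
    }
    mask <- stats::runif(n) < p
    out[[f]][mask] <- NA
  }
  out
}

#' Generate rule-consistent virtual samples
#'
#' Samples records guaranteed to satisfy the antecedent of the chosen
#' guideline rule, labelled with the rule's consequent. The constrained
#' features are clamped to the categories whose numeric ranges intersect
#' the rule's thresholds (and drawn from the intersected range); all other
#' features follow the default generator.
#'
#' @param kb a [knowledge_base()].
#' @param rule_index which rule (1-based index into `kb$rules`).
#' @param n number of samples (0 allowed).
#' @param seed RNG seed.
#' @param config a [synthetic_config()] supplying generator and ranges.
#' @return a cohort data.frame with outcome column.
#' @export
rule_consistent_samples <- function(kb, rule_index, n, seed = 1,
                                    config = synthetic_config(max(n, 1))) {
  if (rule_index < 1 || rule_index > length(kb$rules))
    stop("no such rule: ", rule_index)
  rule <- kb$rules[[rule_index]]
  bn <- config$bn
  outcome <- bn$structure$outcome
  feats <- setdiff(bn$structure$nodes, outcome)
  if (n == 0) {
    out <- as.data.frame(stats::setNames(
      lapply(c(feats, outcome), function(f) numeric(0)), c(feats, outcome)))
    return(out)
  }
  # numeric range of each constrained feature under its literals
  lits_by_feat <- split(rule$literals,
                        vapply(rule$literals, `[[`, character(1), "feature"))
  clamp <- list()
  cut_ranges <- list()
  for (f in names(lits_by_feat)) {
    iv <- .literal_intersection(lits_by_feat[[f]])
    if (is.null(iv)) stop("rule ", rule_index, " has an unsatisfiable antecedent")
    rg <- config$ranges[[f]]
    lo <- pmax(rg$lo, iv$lower); hi <- pmin(rg$hi, iv$upper)
    ok <- lo <= hi
    if (!any(ok))
      stop("antecedent of rule ", rule_index,
           " is unsatisfiable within the plausible ranges of ", f)
    clamp[[f]] <- rg$label[ok]
    cut_ranges[[f]] <- data.frame(label = rg$label[ok], lo = lo[ok],
                                  hi = hi[ok], integer = rg$integer[ok])
  }
  clamp[[outcome]] <- if (rule$consequent == "diabetes") "1" else "0"
  set.seed(seed)
  draws <- .sample_categories(bn, n, clamp = clamp)
  numeric_tab <- list()
  for (f in feats) {
    rg <- if (!is.null(cut_ranges[[f]])) cut_ranges[[f]] else config$ranges[[f]]
    pos <- match(draws[[f]], rg$label)
    lo <- rg$lo[pos]; hi <- rg$hi[pos]
    numeric_tab[[f]] <- if (all(rg$integer))
      floor(stats::runif(n, lo, hi + 1 - 1e-9)) else stats::runif(n, lo, hi)
  }
  numeric_tab[[outcome]] <- as.integer(draws[[outcome]])
  as.data.frame(numeric_tab)
}
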