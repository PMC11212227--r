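#' Knowledge-integration strategies
#'
#' The eight case-study integration strategies, each paired with its purely
#' data-driven counterpart so the harness can compare them on identical
#' folds:
#'
#' * `"discretise"` — decision tree on the raw numeric features vs on the
#'   knowledge-interval discretised, one-hot-encoded features.
#' * `"bn_impute"` — random forest on categorical features with missing
#'   categories filled by the training-fold median category vs by Bayesian
#'   inference on the causal network (restricted to root-complete rows).
#' * `"causal_select"` — random forest on all features vs without the
#'   features only indirectly linked to the outcome (ST in the default DAG).
#' * `"composite"` — decision tree on the original features vs with the
#'   Stumvoll index replacing its three constituents (restricted to rows
#'   observing the constituents).
#' * `"custom_loss"` — neural network with the standard binary
#'   cross-entropy vs with the rule-weighted loss (alpha = 3).
#' * `"rule_tree"` — plain decision tree vs the rule-partitioned tree.
#' * `"ensemble"` — neural network alone vs combined with the rule decision
#'   unit under the sum >= 1 criterion.
#' * `"filter"` — neural network alone vs with predictions contradicting a
#'   firing rule discarded (discards excluded from metric denominators;
#'   discard rate recorded per fold).
#'
#' @name strategies
NULL

.feature_cols <- function(table, kb) {
  intersect(kb$schema$features, names(table))
}

# Baseline numeric preparation: training-fold median imputation.
.fit_numeric <- function(train, kb) {
  feats <- .feature_cols(train, kb)
  medians <- vapply(feats, function(f) {
    obs <- train[[f]][!is.na(train[[f]])]
    if (length(obs) == 0) stop("feature ", f, " fully missing in training fold")
    stats::median(obs)
  }, numeric(1))
  list(feats = feats, medians = medians)
}

.apply_numeric <- function(prep, table) {
  out <- table[, prep$feats, drop = FALSE]
  for (f in prep$feats) out[[f]][is.na(out[[f]])] <- prep$medians[[f]]
  out
}

.v <- function(name, fit, predict) pipeline_variant(name, fit, predict)

.label_pred <- function(model, X) {
  p <- predict_prob(model, X)
  list(prob = p, label = as.integer(p >= 0.5))
}

#' Build the ML / KB-ML variant pair for a strategy
#'
#' @param strategy one of the names in [strategies].
#' @param kb a [knowledge_base()] (default the shipped diabetes one).
#' @return a list with `ml` and `kbml` ([pipeline_variant()]s) and
#'   `prepare`, a function applied to the whole table before
#'   cross-validation (e.g. root-complete filtering).
#' @export
strategy_variants <- function(strategy, kb = default_pima_knowledge()) {
  strategy <- match.arg(strategy, c("discretise", "bn_impute",
                                    "causal_select", "composite",
                                    "custom_loss", "rule_tree",
                                    "ensemble", "filter"))
  outcome <- kb$schema$outcome
  prepare <- identity
  tree_fit <- function(train, seed, transform = NULL, feats = NULL) {
    prep <- .fit_numeric(train, kb)
    if (!is.null(feats)) prep$feats <- intersect(prep$feats, feats)
    X <- .apply_numeric(prep, train)
    if (!is.null(transform)) X <- transform(X)
    model <- train_model(model_spec("decision_tree", seed = seed),
                         X, train[[outcome]])
    list(prep = prep, transform = transform, model = model)
  }
  tree_predict <- function(state, test) {
    X <- .apply_numeric(state$prep, test)
    if (!is.null(state$transform)) X <- state$transform(X)
    .label_pred(state$model, X)
  }
  nn_fit <- function(train, seed, loss = "standard") {
    prep <- .fit_numeric(train, kb)
    X <- .apply_numeric(prep, train)
    rv <- if (loss == "custom") rule_vector(X, kb$rules) else NULL
    model <- train_model(model_spec("neural_net", loss = loss, seed = seed),
                         X, train[[outcome]], rule_vec = rv)
    list(prep = prep, model = model)
  }
  nn_predict <- function(state, test) {
    X <- .apply_numeric(state$prep, test)
    .label_pred(state$model, X)
  }

  switch(strategy,
    discretise = list(
      ml = .v("DT numeric", tree_fit, tree_predict),
      kbml = .v("DT discretised",
        function(train, seed)
          tree_fit(train, seed,
                   transform = function(X) one_hot(discretise(X, kb$scheme))),
        tree_predict),
      prepare = prepare
    ),
    bn_impute = list(
      ml = .v("RF median-category",
        function(train, seed) {
          cat_tr <- discretise(train[, c(.feature_cols(train, kb)),
                                     drop = FALSE], kb$scheme)
          med <- median_categories(cat_tr)
          fill <- function(tab) {
            for (f in names(med)) {
              x <- tab[[f]]
              x[is.na(x)] <- med[[f]]
              tab[[f]] <- x
            }
            tab
          }
          model <- train_model(model_spec("random_forest", seed = seed),
                               fill(cat_tr), train[[outcome]])
          list(med = med, model = model)
        },
        function(state, test) {
          cat_te <- discretise(test[, intersect(kb$schema$features,
                                                names(test)), drop = FALSE],
                               kb$scheme)
          for (f in names(state$med)) {
            x <- cat_te[[f]]; x[is.na(x)] <- state$med[[f]]
            cat_te[[f]] <- x
          }
          .label_pred(state$model, cat_te)
        }),
      kbml = .v("RF BN-imputed",
        function(train, seed) {
          feats <- .feature_cols(train, kb)
          cat_tr <- discretise(train[, feats, drop = FALSE], kb$scheme)
          cat_tr[[outcome]] <- factor(train[[outcome]], levels = c(0, 1))
          bn <- fit_cpts(cat_tr, kb$structure, smoothing = 1,
                         scheme = kb$scheme)
          med <- median_categories(cat_tr[, feats, drop = FALSE])
          imp_tr <- bn_impute(cat_tr, bn, med)
          model <- train_model(model_spec("random_forest", seed = seed),
                               imp_tr[, feats, drop = FALSE],
                               train[[outcome]])
          list(bn = bn, med = med, model = model, feats = feats)
        },
        function(state, test) {
          cat_te <- discretise(test[, state$feats, drop = FALSE], kb$scheme)
          # outcome column omitted: the network marginalises over it, so
          # test labels never leak into imputation
          imp_te <- bn_impute(cat_te, state$bn, state$med)
          .label_pred(state$model, imp_te)
        }),
      prepare = function(table) filter_root_complete(table, kb$structure)
    ),
    causal_select = list(
      ml = .v("RF all features",
        function(train, seed) {
          prep <- .fit_numeric(train, kb)
          X <- .apply_numeric(prep, train)
          model <- train_model(model_spec("random_forest", seed = seed),
                               X, train[[outcome]])
          list(prep = prep, model = model)
        },
        function(state, test)
          .label_pred(state$model, .apply_numeric(state$prep, test))),
      kbml = .v("RF causal subset",
        function(train, seed) {
          kept <- causal_feature_select(kb$structure)$kept
          prep <- .fit_numeric(train, kb)
          prep$feats <- intersect(prep$feats, kept)
          X <- .apply_numeric(prep, train)
          model <- train_model(model_spec("random_forest", seed = seed),
                               X, train[[outcome]])
          list(prep = prep, model = model)
        },
        function(state, test)
          .label_pred(state$model, .apply_numeric(state$prep, test))),
      prepare = prepare
    ),
    composite = list(
      ml = .v("DT original", tree_fit, tree_predict),
      kbml = .v("DT Stumvoll",
        function(train, seed)
          tree_fit(train, seed,
                   transform = function(X)
                     compute_index(X, kb$formulas[[1]], replace = TRUE)),
        tree_predict),
      prepare = function(table) {
        feats <- names(kb$formulas[[1]]$coefficients)
        keep <- stats::complete.cases(table[, feats, drop = FALSE])
        out <- table[keep, , drop = FALSE]
        attr(out, "retained_fraction") <- mean(keep)
        out
      }
    ),
    custom_loss = list(
      ml = .v("NN standard loss",
              function(train, seed) nn_fit(train, seed, "standard"),
              nn_predict),
      kbml = .v("NN custom loss",
                function(train, seed) nn_fit(train, seed, "custom"),
                nn_predict),
      prepare = prepare
    ),
    rule_tree = list(
      ml = .v("DT plain", tree_fit, tree_predict),
      kbml = .v("Rule-seeded tree",
        function(train, seed) {
          prep <- .fit_numeric(train, kb)
          X <- .apply_numeric(prep, train)
          model <- train_model(
            model_spec("rule_seeded_tree", rules = kb$rules, seed = seed),
            X, train[[outcome]])
          list(prep = prep, model = model)
        },
        function(state, test)
          .label_pred(state$model, .apply_numeric(state$prep, test))),
      prepare = prepare
    ),
    ensemble = list(
      ml = .v("NN alone",
              function(train, seed) nn_fit(train, seed, "standard"),
              nn_predict),
      kbml = .v("NN + rule ensemble",
        function(train, seed) nn_fit(train, seed, "standard"),
        function(state, test) {
          X <- .apply_numeric(state$prep, test)
          p <- predict_prob(state$model, X)
          score <- rule_decision_unit(X, kb$rules)
          list(prob = (score + p) / 2,
               label = ensemble_combine(score, p, threshold = 1))
        }),
      prepare = prepare
    ),
    filter = list(
      ml = .v("NN alone",
              function(train, seed) nn_fit(train, seed, "standard"),
              nn_predict),
      kbml = .v("NN + output filter",
        function(train, seed) nn_fit(train, seed, "standard"),
        function(state, test) {
          X <- .apply_numeric(state$prep, test)
          p <- predict_prob(state$model, X)
          lab <- as.integer(p >= 0.5)
          flt <- output_filter(lab, rule_vector(X, kb$rules))
          list(prob = p, label = lab, keep = flt$status == "keep")
        }),
      prepare = prepare
    )
  )
}

#' Run one strategy comparison
#'
#' Applies the strategy's table preparation (e.g. root-complete filtering),
#' runs the paired repeated stratified CV of its ML and KB-ML variants, and
#' computes the corrected-t comparison.
#'
#' @param table labelled cohort data.frame (implausible zeros already
#'   marked).
#' @param strategy strategy name (see [strategies]).
#' @param kb a [knowledge_base()].
#' @param config a [cv_config()].
#' @return a list with `cv` (`paired_cv`) and `comparison`
#'   (`comparison_result`).
#' @export
run_strategy_comparison <- function(table, strategy,
                                    kb = default_pima_knowledge(),
                                    config = cv_config()) {
  sv <- strategy_variants(strategy, kb)
  tab <- sv$prepare(table)
  cv <- repeated_stratified_cv(sv$ml, sv$kbml, tab, config,
                               outcome = kb$schema$outcome)
  list(cv = cv, comparison = compare_cv(cv))
}

#' Run the full strategy comparison grid
#'
#' Runs every requested strategy and assembles the mean/sd comparison grid
#' with significance stars.
#'
#' @param table labelled cohort data.frame.
#' @param kb a [knowledge_base()].
#' @param strategies strategy names (default all eight).
#' @param config a [cv_config()].
#' @param verbose print per-strategy progress to stderr.
#' @return a list with `table` (a [comparison_table()]) and `runs` (the
#'   per-strategy results).
#' @export
run_comparison_grid <- function(table, kb = default_pima_knowledge(),
                                strategies = c("discretise", "bn_impute",
                                               "causal_select", "composite",
                                               "custom_loss", "rule_tree",
                                               "ensemble", "filter"),
                                config = cv_config(), verbose = FALSE) {
  runs <- list()
  for (s in strategies) {
    if (verbose) message("strategy: ", s)
    runs[[s]] <- run_strategy_comparison(table, s, kb, config)
  }
  list(table = comparison_table(runs), runs = runs)
}
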