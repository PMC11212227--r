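#' Model specification
#'
#' Hyperparameters of the supported learners. Defaults follow the case
#' study: trees and forests with maximum depth 10, minimum sample split 5
#' and balanced class weights; a 3-layer feed-forward network (two ReLU
#' hidden layers, sigmoid output) trained with batch size 20 for 24 epochs.
#' Hidden widths (12, 8) and the Adam learning rate 0.001 are package
#' defaults, configurable here.
#'
#' @param kind `"decision_tree"`, `"random_forest"`, `"neural_net"` or
#'   `"rule_seeded_tree"`.
#' @param max_depth maximum tree depth.
#' @param min_split minimum number of samples to attempt a split.
#' @param class_weight `"balanced"` or `"none"`.
#' @param num_trees forest size.
#' @param hidden integer vector of the two hidden-layer widths.
#' @param batch_size,epochs,learning_rate network training parameters.
#' @param loss `"standard"` or `"custom"` (rule-weighted, needs a rule
#'   vector at fit time).
#' @param alpha scaling factor of the custom loss.
#' @param rules list of [logic_rule()]s, required for
#'   `"rule_seeded_tree"`.
#' @param seed RNG seed for fitting.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(kind = c("decision_tree", "random_forest",
                                "neural_net", "rule_seeded_tree"),
                       max_depth = 10, min_split = 5,
                       class_weight = c("balanced", "none"),
                       num_trees = 100,
                       hidden = c(12, 8), batch_size = 20, epochs = 24,
                       learning_rate = 1e-3,
                       loss = c("standard", "custom"), alpha = 3,
                       rules = NULL, seed = 1) {
  out <- list(kind = match.arg(kind), max_depth = max_depth,
              min_split = min_split, class_weight = match.arg(class_weight),
              num_trees = num_trees, hidden = hidden,
              batch_size = batch_size, epochs = epochs,
              learning_rate = learning_rate, loss = match.arg(loss),
              alpha = alpha, rules = rules, seed = seed)
  class(out) <- "model_spec"
  out
}

.balanced_weights <- function(y) {
  n <- length(y); n1 <- sum(y == 1); n0 <- n - n1
  ifelse(y == 1, n / (2 * max(n1, 1)), n / (2 * max(n0, 1)))
}

#' Train a predictor
#'
#' Fits the learner described by `spec` on a feature table and 0/1 labels.
#' All fits are deterministic given identical inputs and `spec$seed`. For
#' the custom rule-weighted loss the optimiser minimises [ctl()]; a rule
#' vector must then be supplied. Neural networks min-max scale their inputs
#' internally using training-fold ranges.
#'
#' @param spec a [model_spec()].
#' @param features feature data.frame (numeric and/or factor columns; the
#'   network requires numeric).
#' @param labels 0/1 outcome vector.
#' @param rule_vec optional rule vector from [rule_vector()].
#' @return a fitted model of class `informed_model` with a [predict_prob()]
#'   method.
#' @export
train_model <- function(spec, features, labels, rule_vec = NULL) {
  if (nrow(features) == 0) stop("empty training data")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  out <- switch(spec$kind,
    decision_tree = .fit_tree(spec, features, labels),
    random_forest = .fit_forest(spec, features, labels),
    neural_net = .fit_nnet(spec, features, labels, rule_vec),
    rule_seeded_tree = {
      if (is.null(spec$rules)) stop("rule_seeded_tree requires spec$rules")
      rule_seeded_tree_fit(features, labels, spec$rules, spec)
    })
  out$spec <- spec
  out
}

# Column names like "G120=Low" (one-hot blocks) are not syntactic; model
# fitting uses sanitised names and predictions map back through `safe`.
.safe_df <- function(features) {
  df <- features
  names(df) <- make.names(names(df), unique = TRUE)
  df
}

.fit_tree <- function(spec, features, labels) {
  df <- .safe_df(features)
  df$.y <- factor(labels, levels = c(0, 1))
  w <- if (spec$class_weight == "balanced") .balanced_weights(labels)
       else rep(1, length(labels))
  set.seed(spec$seed)
  fit <- rpart::rpart(
    .y ~ ., data = df, weights = w, method = "class",
    control = rpart::rpart.control(maxdepth = spec$max_depth,
                                   minsplit = spec$min_split,
                                   minbucket = 1, cp = 0, xval = 0)
  )
  out <- list(fit = fit, columns = names(features))
  class(out) <- c("kb_tree", "informed_model")
  out
}

.fit_forest <- function(spec, features, labels) {
  df <- .safe_df(features)
  df$.y <- factor(labels, levels = c(0, 1))
  cw <- if (spec$class_weight == "balanced") {
    n <- length(labels); n1 <- sum(labels == 1); n0 <- n - n1
    c(n / (2 * max(n0, 1)), n / (2 * max(n1, 1)))
  } else c(1, 1)
  fit <- ranger::ranger(
    dependent.variable.name = ".y", data = df,
    probability = TRUE, num.trees = spec$num_trees,
    max.depth = spec$max_depth, min.node.size = spec$min_split,
    class.weights = cw, seed = spec$seed, num.threads = 1
  )
  out <- list(fit = fit, columns = names(features))
  class(out) <- c("kb_forest", "informed_model")
  out
}

.fit_nnet <- function(spec, features, labels, rule_vec) {
  if (spec$loss == "custom" && is.null(rule_vec))
    stop("custom loss requires a rule vector")
  num <- vapply(features, is.numeric, logical(1))
  if (!all(num)) stop("neural_net requires numeric features")
  X <- as.matrix(features)
  lo <- apply(X, 2, min); hi <- apply(X, 2, max)
  rng <- ifelse(hi > lo, hi - lo, 1)
  Xs <- sweep(sweep(X, 2, lo), 2, rng, `/`)
  Xs[, hi == lo] <- 0
  par <- .nn_train(Xs, labels, r = rule_vec, hidden = spec$hidden,
                   batch_size = spec$batch_size, epochs = spec$epochs,
                   lr = spec$learning_rate, alpha = spec$alpha,
                   loss = spec$loss, seed = spec$seed)
  out <- list(par = par, lo = lo, rng = rng, constant = hi == lo,
              columns = names(features))
  class(out) <- c("kb_nnet", "informed_model")
  out
}

#' Predicted probability of the positive class
#'
#' @param model a fitted `informed_model`.
#' @param newdata feature data.frame.
#' @return numeric vector of probabilities in [0, 1].
#' @export
predict_prob <- function(model, newdata) UseMethod("predict_prob")

#' @export
predict_prob.kb_tree <- function(model, newdata) {
  nd <- .safe_df(newdata[, model$columns, drop = FALSE])
  p <- predict(model$fit, newdata = nd, type = "prob")
  as.numeric(p[, "1"])
}

#' @export
predict_prob.kb_forest <- function(model, newdata) {
  nd <- .safe_df(newdata[, model$columns, drop = FALSE])
  p <- predict(model$fit, data = nd, num.threads = 1)$predictions
  as.numeric(p[, "1"])
}

#' @export
predict_prob.kb_nnet <- function(model, newdata) {
  X <- as.matrix(newdata[, model$columns, drop = FALSE])
  Xs <- sweep(sweep(X, 2, model$lo), 2, model$rng, `/`)
  Xs <- pmin(pmax(Xs, 0), 1)  # arg order keeps the matrix dims
  Xs[, model$constant] <- 0
  .nn_forward(model$par, Xs)$p
}

#' @export
predict.informed_model <- function(object, newdata,
                                   type = c("prob", "class"), ...) {
  type <- match.arg(type)
  p <- predict_prob(object, newdata)
  if (type == "prob") p else as.integer(p >= 0.5)
}

#' @export
print.informed_model <- function(x, ...) {
  cat("Fitted", x$spec$kind, "on", length(x$columns), "features\n")
  invisible(x)
}

#' Fit a rule-partitioned decision tree
#'
#' Seeds a decision tree's first splits with the two guideline rules: the
#' training data is partitioned into the samples satisfying the diabetes
#' rule, those satisfying the healthy rule, and the remainder, and a
#' separate tree is grown on each partition. A partition whose labels are
#' constant (or which is empty) stores a constant predictor — for an empty
#' partition, the seeding rule's consequent.
#'
#' @param features numeric feature data.frame (must include the rule
#'   features).
#' @param labels 0/1 outcome vector.
#' @param rules list of the two [logic_rule()]s.
#' @param spec a [model_spec()] supplying the tree hyperparameters.
#' @return an object of class `kb_rule_tree` (an `informed_model`).
#' @export
rule_seeded_tree_fit <- function(features, labels, rules,
                                 spec = model_spec("decision_tree")) {
  r <- rule_vector(features, rules)
  part_of <- ifelse(!is.na(r) & r == 1, "rule1",
                    ifelse(!is.na(r) & r == 0, "rule2", "rest"))
  consequents <- c(rule1 = 1, rule2 = 0, rest = NA)
  tree_spec <- model_spec("decision_tree", max_depth = spec$max_depth,
                          min_split = spec$min_split,
                          class_weight = spec$class_weight,
                          seed = spec$seed)
  submodels <- list()
  for (pt in c("rule1", "rule2", "rest")) {
    idx <- which(part_of == pt)
    if (length(idx) == 0) {
      const <- consequents[[pt]]
      if (is.na(const)) const <- as.integer(mean(labels) >= 0.5)
      submodels[[pt]] <- list(type = "constant", label = const)
    } else if (length(unique(labels[idx])) == 1) {
      submodels[[pt]] <- list(type = "constant", label = labels[idx][1])
    } else {
      submodels[[pt]] <- list(
        type = "tree",
        model = .fit_tree(tree_spec, features[idx, , drop = FALSE],
                          labels[idx]))
    }
  }
  out <- list(rules = rules, submodels = submodels, columns = names(features))
  class(out) <- c("kb_rule_tree", "informed_model")
  out
}

#' @export
predict_prob.kb_rule_tree <- function(model, newdata) {
  r <- rule_vector(newdata, model$rules)
  part_of <- ifelse(!is.na(r) & r == 1, "rule1",
                    ifelse(!is.na(r) & r == 0, "rule2", "rest"))
  p <- numeric(nrow(newdata))
  for (pt in c("rule1", "rule2", "rest")) {
    idx <- which(part_of == pt)
    if (length(idx) == 0) next
    sm <- model$submodels[[pt]]
    p[idx] <- if (sm$type == "constant") sm$label
              else predict_prob(sm$model, newdata[idx, , drop = FALSE])
  }
  p
}
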