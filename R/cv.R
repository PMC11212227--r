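#' Cross-validation configuration
#'
#' @param repeats number of CV repetitions (default 10).
#' @param folds folds per repetition (default 10, >= 2).
#' @param stratified stratify folds by outcome (default `TRUE`).
#' @param seed master seed; fold assignments and model fits derive from it.
#' @return an object of class `cv_config`.
#' @export
cv_config <- function(repeats = 10, folds = 10, stratified = TRUE, seed = 1) {
  if (folds < 2) stop("folds must be >= 2")
  out <- list(repeats = repeats, folds = folds, stratified = stratified,
              seed = seed)
  class(out) <- "cv_config"
  out
}

#' Pipeline variant
#'
#' A named fit/predict pair evaluated by the CV harness. `fit(train, seed)`
#' receives the training rows (a cohort data.frame including the outcome
#' column) and returns any state; `predict(state, test)` returns a list
#' with `prob`, `label` and optionally `keep` (a logical vector marking
#' predictions retained for scoring — used by the output-filtering hybrid,
#' whose discarded predictions are excluded from metric denominators).
#'
#' @param name display name.
#' @param fit function(train, seed).
#' @param predict function(state, test).
#' @return an object of class `pipeline_variant`.
#' @export
pipeline_variant <- function(name, fit, predict) {
  out <- list(name = name, fit = fit, predict = predict)
  class(out) <- "pipeline_variant"
  out
}

#' Stratified fold assignment
#'
#' Assigns each sample to one of `k` folds. With stratification, samples of
#' each class are shuffled and dealt round-robin, so every fold's class
#' count is within one sample of the proportional share.
#'
#' @param y outcome vector.
#' @param k number of folds.
#' @param seed RNG seed.
#' @param stratified stratify by `y` (default `TRUE`).
#' @return integer vector of fold ids in `1:k`.
#' @export
stratified_folds <- function(y, k, seed = 1, stratified = TRUE) {
  n <- length(y)
  if (k > n) stop("more folds than samples")
  set.seed(seed)
  fold <- integer(n)
  groups <- if (stratified) split(seq_len(n), y) else list(seq_len(n))
  for (g in groups) {
    g <- g[sample.int(length(g))]
    fold[g] <- rep_len(seq_len(k), length(g))
  }
  fold
}

.metrics_row <- function(y_true, y_pred, y_prob) {
  m <- compute_metrics(y_true, y_pred, y_prob)
  as.data.frame(m)
}

#' Paired repeated stratified cross-validation of two pipeline variants
#'
#' Evaluates both variants on identical fold assignments (a paired design,
#' required for the corrected paired t-test). Per (repeat, fold), each
#' variant is fitted on the training rows and scored on the test rows with
#' [compute_metrics()]. Deterministic given `config$seed`; both variants
#' receive the same derived fit seed in each fold, so two variants sharing
#' a learner train identically.
#'
#' @param variant_a,variant_b [pipeline_variant()]s.
#' @param table labelled cohort data.frame (outcome column present).
#' @param config a [cv_config()].
#' @param outcome outcome column name.
#' @return a list of class `paired_cv` with elements `a` and `b`
#'   (data.frames of per-fold metrics, class `fold_results`), `assignments`
#'   (repeats x n matrix of fold ids), `rho` (mean test/train size ratio)
#'   and `extras` (per-fold list of variant-b prediction details).
#' @export
repeated_stratified_cv <- function(variant_a, variant_b, table,
                                   config = cv_config(),
                                   outcome = "Outcome") {
  y <- table[[outcome]]
  if (is.null(y) || anyNA(y)) stop("table must be fully labelled")
  n <- nrow(table)
  res_a <- list(); res_b <- list()
  assignments <- matrix(NA_integer_, nrow = config$repeats, ncol = n)
  ratios <- numeric(0)
  for (rep_id in seq_len(config$repeats)) {
    fold <- stratified_folds(y, config$folds, seed = config$seed + rep_id,
                             stratified = config$stratified)
    assignments[rep_id, ] <- fold
    for (f in seq_len(config$folds)) {
      test_idx <- which(fold == f)
      train_idx <- which(fold != f)
      if (length(unique(y[train_idx])) < 2)
        stop("a class is absent from the training fold (repeat ", rep_id,
             ", fold ", f, ")")
      fit_seed <- config$seed + 101L * rep_id + f
      train <- table[train_idx, , drop = FALSE]
      test <- table[test_idx, , drop = FALSE]
      ratios <- c(ratios, length(test_idx) / length(train_idx))
      for (side in c("a", "b")) {
        variant <- if (side == "a") variant_a else variant_b
        state <- variant$fit(train, fit_seed)
        pred <- variant$predict(state, test)
        keep <- if (is.null(pred$keep)) rep(TRUE, length(test_idx)) else pred$keep
        row <- .metrics_row(y[test_idx][keep], pred$label[keep],
                            pred$prob[keep])
        row$rep <- rep_id; row$fold <- f
        row$discard_rate <- 1 - mean(keep)
        if (side == "a") res_a[[length(res_a) + 1]] <- row
        else res_b[[length(res_b) + 1]] <- row
      }
    }
  }
  a <- do.call(rbind, res_a); b <- do.call(rbind, res_b)
  class(a) <- c("fold_results", class(a))
  class(b) <- c("fold_results", class(b))
  out <- list(a = a, b = b, assignments = assignments, rho = mean(ratios),
              names = c(variant_a$name, variant_b$name))
  class(out) <- "paired_cv"
  out
}

#' Compare the two arms of a paired CV run
#'
#' Per metric: mean and standard deviation for both variants, the
#' Nadeau-Bengio corrected paired t statistic and p-value, and a
#' significance star annotation attached to the better-performing side.
#' `rho` defaults to the actual mean test/train size ratio of the run.
#'
#' @param cv a `paired_cv` from [repeated_stratified_cv()].
#' @param rho test/train ratio for the correction (default from `cv`).
#' @return a data.frame of class `comparison_result` with one row per
#'   metric.
#' @export
compare_cv <- function(cv, rho = cv$rho) {
  rows <- lapply(.metric_names, function(m) {
    xa <- cv$a[[m]]; xb <- cv$b[[m]]
    ok <- !is.na(xa) & !is.na(xb)
    xa <- xa[ok]; xb <- xb[ok]
    d <- xb - xa
    tt <- nb_ttest(d, rho = rho)
    stars <- significance_stars(tt$p)
    data.frame(
      metric = m,
      mean_a = mean(xa), sd_a = stats::sd(xa),
      mean_b = mean(xb), sd_b = stats::sd(xb),
      t = tt$t, p = tt$p, k = length(d),
      stars_a = if (tt$mean_d < 0) stars else "",
      stars_b = if (tt$mean_d > 0) stars else "",
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "names_ab") <- cv$names
  class(out) <- c("comparison_result", class(out))
  out
}

#' Build a comparison report across strategies
#'
#' Assembles per-strategy [compare_cv()] results into one long table (the
#' machine-readable form of a mean/sd comparison grid), with significance
#' stars attached to the significantly better side.
#'
#' @param results named list; each element is a `paired_cv` or a list with
#'   elements `cv` (the `paired_cv`) and optionally `comparison`.
#' @return a data.frame of class `comparison_table` with columns
#'   `strategy`, `metric`, `ml_mean`, `ml_sd`, `ml_stars`, `kbml_mean`,
#'   `kbml_sd`, `kbml_stars`, `t`, `p`.
#' @export
comparison_table <- function(results) {
  rows <- lapply(names(results), function(nm) {
    x <- results[[nm]]
    cv <- if (inherits(x, "paired_cv")) x else x$cv
    cmp <- if (!inherits(x, "paired_cv") && !is.null(x$comparison))
      x$comparison else compare_cv(cv)
    data.frame(
      strategy = nm, metric = cmp$metric,
      ml_mean = cmp$mean_a, ml_sd = cmp$sd_a, ml_stars = cmp$stars_a,
      kbml_mean = cmp$mean_b, kbml_sd = cmp$sd_b, kbml_stars = cmp$stars_b,
      t = cmp$t, p = cmp$p, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("comparison_table", class(out))
  out
}

#' @export
print.comparison_table <- function(x, digits = 3, ...) {
  for (s in unique(x$strategy)) {
    cat("==", s, "==\n")
    sub <- x[x$strategy == s, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      cat(sprintf("  %-18s ML %0.*f (%0.*f)%-3s  KB-ML %0.*f (%0.*f)%-3s  p=%.4f\n",
                  sub$metric[i], digits, sub$ml_mean[i], digits, sub$ml_sd[i],
                  sub$ml_stars[i], digits, sub$kbml_mean[i], digits,
                  sub$kbml_sd[i], sub$kbml_stars[i], sub$p[i]))
    }
  }
  invisible(x)
}

#' Write a comparison table to CSV
#'
#' @param x a `comparison_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Data-efficiency analysis
#'
#' Repeats the paired CV comparison of two variants on `n_draws` random
#' subsets of the cohort (the limited-data regime), reporting the per-draw
#' comparisons and across-draw metric means for both variants.
#'
#' @param variant_a,variant_b [pipeline_variant()]s.
#' @param table labelled cohort data.frame.
#' @param subset_size rows per draw (<= nrow(table)).
#' @param n_draws number of random subsets.
#' @param config a [cv_config()] for each draw.
#' @param seed seed for the subset draws.
#' @return a list with `draws` (list of `paired_cv`), `summary`
#'   (data.frame of across-draw means per metric and variant).
#' @export
data_efficiency <- function(variant_a, variant_b, table, subset_size,
                            n_draws = 5, config = cv_config(), seed = 1) {
  if (subset_size > nrow(table)) stop("subset_size exceeds table size")
  draws <- list()
  for (i in seq_len(n_draws)) {
    set.seed(seed + i)
    idx <- if (subset_size == nrow(table)) seq_len(nrow(table))
           else sample.int(nrow(table), subset_size)
    cfg <- config
    cfg$seed <- config$seed + 1000L * i
    draws[[i]] <- repeated_stratified_cv(variant_a, variant_b,
                                         table[idx, , drop = FALSE], cfg)
  }
  summary <- do.call(rbind, lapply(.metric_names, function(m) {
    data.frame(
      metric = m,
      mean_a = mean(vapply(draws, function(d) mean(d$a[[m]], na.rm = TRUE),
                           numeric(1))),
      mean_b = mean(vapply(draws, function(d) mean(d$b[[m]], na.rm = TRUE),
                           numeric(1))),
      stringsAsFactors = FALSE
    )
  }))
  list(draws = draws, summary = summary)
}
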