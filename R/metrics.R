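#' Classification metric set
#'
#' Computes accuracy, balanced accuracy, precision, recall, F1, ROC-AUC and
#' the Matthews correlation coefficient from predictions on a binary
#' outcome. Conventions for degenerate cases: precision with no positive
#' predictions is 0; recall/specificity with an empty class is 0; MCC with
#' a zero denominator is 0; ROC-AUC needs `y_prob` and both classes, else
#' `NA`. ROC-AUC uses the midrank (Mann-Whitney) convention for ties.
#'
#' @param y_true 0/1 truth vector.
#' @param y_pred 0/1 prediction vector.
#' @param y_prob optional probability vector for ROC-AUC.
#' @return a named list with elements `accuracy`, `balanced_accuracy`,
#'   `precision`, `recall`, `f1`, `roc_auc`, `mcc`.
#' @export
compute_metrics <- function(y_true, y_pred, y_prob = NULL) {
  n <- length(y_true)
  if (length(y_pred) != n) stop("y_true and y_pred lengths differ")
  if (!is.null(y_prob) && length(y_prob) != n)
    stop("y_true and y_prob lengths differ")
  tp <- sum(y_true == 1 & y_pred == 1)
  fp <- sum(y_true == 0 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == 0)
  tn <- sum(y_true == 0 & y_pred == 0)
  acc <- (tp + tn) / n
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  spec <- if (tn + fp == 0) 0 else tn / (tn + fp)
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  ba <- (rec + spec) / 2
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
  auc <- NA_real_
  if (!is.null(y_prob)) {
    n1 <- sum(y_true == 1); n0 <- sum(y_true == 0)
    if (n1 > 0 && n0 > 0) {
      r <- rank(y_prob)   # midranks
      auc <- (sum(r[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    }
  }
  list(accuracy = acc, balanced_accuracy = ba, precision = prec,
       recall = rec, f1 = f1, roc_auc = auc, mcc = mcc)
}

.metric_names <- c("accuracy", "balanced_accuracy", "precision", "recall",
                   "f1", "roc_auc", "mcc")

#' Nadeau-Bengio corrected paired t-test
#'
#' Paired t-test over k per-fold metric differences from repeated
#' cross-validation, with the variance inflated by `1/k + rho` (rho =
#' test/train size ratio, 1/9 for 10-fold CV) to correct for the overlap of
#' training sets across folds. Degrees of freedom k - 1.
#'
#' @param d vector of paired per-fold differences (k >= 2).
#' @param rho test/train size ratio (>= 0; 0 recovers the standard paired
#'   t-test).
#' @return a list with `t`, `p` (two-sided), `df`, `mean_d`, `sd_d`, `rho`.
#' @export
nb_ttest <- function(d, rho = 1 / 9) {
  k <- length(d)
  if (k < 2) stop("need at least 2 paired differences")
  if (rho < 0) stop("rho must be non-negative")
  dbar <- mean(d)
  s2 <- stats::var(d)
  if (s2 == 0) {
    if (dbar == 0) return(list(t = 0, p = 1, df = k - 1, mean_d = 0,
                               sd_d = 0, rho = rho))
    warning("zero variance with nonzero mean difference; p = 0")
    return(list(t = sign(dbar) * Inf, p = 0, df = k - 1, mean_d = dbar,
                sd_d = 0, rho = rho))
  }
  t_stat <- dbar / sqrt((1 / k + rho) * s2)
  p <- 2 * stats::pt(-abs(t_stat), df = k - 1)
  list(t = t_stat, p = p, df = k - 1, mean_d = dbar, sd_d = sqrt(s2),
       rho = rho)
}

#' Significance stars
#'
#' `"***"`, `"**"`, `"*"` for p below 0.01, 0.05, 0.1 respectively;
#' otherwise the empty string.
#'
#' @param p two-sided p-value in [0, 1].
#' @return a string annotation.
#' @export
significance_stars <- function(p) {
  if (is.na(p)) return("")
  if (p < 0 || p > 1) stop("p must be in [0, 1]")
  if (p < 0.01) "***" else if (p < 0.05) "**" else if (p < 0.1) "*" else ""
}

#' Guideline adherence analysis
#'
#' Over the samples "correctly handled by the guidelines" — those where a
#' rule fires and the rule's consequent equals the true label — reports the
#' fraction the model predicts correctly (adherence). Also reports rule
#' coverage (fraction of all samples where any rule fires) and rule
#' correctness (fraction of all samples where a firing rule's consequent
#' equals the label).
#'
#' @param predictions 0/1 model predictions.
#' @param rule_verdicts numeric rule vector (1 / 0 / `NA`).
#' @param labels 0/1 truth vector.
#' @return a list with `adherence` (`NA` if no qualifying samples),
#'   `coverage`, `rule_correctness`, `n_qualifying`.
#' @export
guideline_adherence <- function(predictions, rule_verdicts, labels) {
  n <- length(labels)
  stopifnot(length(predictions) == n, length(rule_verdicts) == n)
  fires <- !is.na(rule_verdicts)
  qualifying <- fires & rule_verdicts == labels
  list(
    adherence = if (!any(qualifying)) NA_real_
                else mean(predictions[qualifying] == labels[qualifying]),
    coverage = if (n == 0) NA_real_ else mean(fires),
    rule_correctness = if (n == 0) NA_real_ else mean(qualifying),
    n_qualifying = sum(qualifying)
  )
}
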