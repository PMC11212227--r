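#' Rule-based decision unit
#'
#' Maps the tri-state rule verdict of each record to a probability-like
#' score: 1 when the diabetes rule fires, 0 when the healthy rule fires,
#' 0.5 for all other (intermediate) cases.
#'
#' @param table feature data.frame (or a single named record).
#' @param rules list of [logic_rule()]s.
#' @return numeric vector over {1, 0.5, 0}.
#' @export
rule_decision_unit <- function(table, rules) {
  if (!is.data.frame(table)) table <- as.data.frame(as.list(table))
  r <- rule_vector(table, rules)
  ifelse(is.na(r), 0.5, r)
}

#' Sum-threshold rule/model ensemble
#'
#' Classifies a sample as diabetic iff the sum of the rule unit's score and
#' the model's predicted probability reaches the threshold. At the default
#' threshold 1 every sample the diabetes rule covers is classified diabetic
#' regardless of the model; a threshold above 1 lets the model affect only
#' the rules' intermediate cases, while a lower threshold lets the model
#' overrule the rule unit.
#'
#' @param rule_score output of [rule_decision_unit()].
#' @param model_prob model probability in [0, 1].
#' @param threshold decision threshold on the sum, in [0, 2] (default 1).
#' @return integer labels (1 = diabetic, 0 = healthy).
#' @export
ensemble_combine <- function(rule_score, model_prob, threshold = 1) {
  if (any(model_prob < 0 | model_prob > 1)) stop("model_prob must be in [0, 1]")
  if (threshold < 0 || threshold > 2) stop("threshold must be in [0, 2]")
  as.integer(rule_score + model_prob >= threshold)
}

#' Series output filter
#'
#' Cross-checks model predictions against the rule verdicts: a prediction
#' contradicting a firing rule (model says healthy where the diabetes rule
#' fires, or diabetic where the healthy rule fires) is discarded (or merely
#' flagged). Predictions outside the rules' scope are always kept, so after
#' discarding, no retained prediction contradicts a firing rule.
#'
#' @param model_label predicted 0/1 labels.
#' @param rule_verdict verdicts: `"positive"`, `"negative"`, `"abstain"`, or
#'   the numeric rule vector (1 / 0 / `NA`).
#' @param action `"discard"` (default) or `"flag"` (keep everything, mark
#'   contradictions).
#' @return a data.frame with columns `label`, `verdict`, `status`
#'   (`"keep"` / `"discard"` / `"flag"`); attribute `"discard_rate"` gives
#'   the contradicting fraction.
#' @export
output_filter <- function(model_label, rule_verdict,
                          action = c("discard", "flag")) {
  action <- match.arg(action)
  if (is.numeric(rule_verdict)) {
    rule_verdict <- ifelse(is.na(rule_verdict), "abstain",
                           ifelse(rule_verdict == 1, "positive", "negative"))
  }
  contra <- (rule_verdict == "positive" & model_label == 0) |
            (rule_verdict == "negative" & model_label == 1)
  status <- rep("keep", length(model_label))
  status[contra] <- if (action == "discard") "discard" else "flag"
  out <- data.frame(label = model_label, verdict = rule_verdict,
                    status = status, stringsAsFactors = FALSE)
  attr(out, "discard_rate") <-
    if (length(contra) == 0) 0 else mean(contra)
  out
}
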