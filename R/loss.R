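#' Loss specification for rule-weighted training
#'
#' @param alpha non-negative scaling factor controlling how strongly samples
#'   correctly handled by the guideline rules are upweighted; the case-study
#'   value is 3.
#' @param epsilon probability clip inside the log (0 < epsilon < 0.5).
#' @return an object of class `loss_spec`.
#' @export
loss_spec <- function(alpha = 3, epsilon = 1e-7) {
  if (!is.numeric(alpha) || alpha < 0) stop("alpha must be non-negative")
  if (!(epsilon > 0 && epsilon < 0.5)) stop("epsilon must be in (0, 0.5)")
  out <- list(alpha = alpha, epsilon = epsilon)
  class(out) <- "loss_spec"
  out
}

#' Rule vector
#'
#' Per-sample tri-state verdict of the two guideline rules computed on the
#' (imputed) numeric features: 1 if the sample satisfies the diabetes rule's
#' antecedent, 0 if it satisfies the healthy rule's antecedent, `NA`
#' otherwise.
#'
#' @param table feature data.frame.
#' @param rules list of the two [logic_rule()]s (one diabetes, one healthy).
#' @return numeric vector of 1 / 0 / `NA`, length `nrow(table)`.
#' @export
rule_vector <- function(table, rules) {
  n <- nrow(table)
  r <- rep(NA_real_, n)
  if (n == 0) return(r)
  names(table) <- canonical_features(names(table))
  for (rule in rules) {
    sat <- rep(TRUE, n)
    for (lit in rule$literals) {
      v <- table[[lit$feature]]
      if (is.null(v)) { sat <- rep(FALSE, n); break }
      h <- switch(lit$op,
        "<=" = v <= lit$threshold, ">=" = v >= lit$threshold,
        "<"  = v <  lit$threshold, ">"  = v >  lit$threshold)
      h[is.na(h)] <- FALSE
      sat <- sat & h
    }
    r[sat] <- if (rule$consequent == "diabetes") 1 else 0
  }
  r
}

#' Custom sample loss (rule-weighted binary cross-entropy)
#'
#' Binary cross-entropy `L(y, p) = -[y log p + (1-y) log(1-p)]` (natural
#' log, probabilities clipped to `[epsilon, 1-epsilon]`), multiplied by
#' `(alpha + 1)` when the sample's rule verdict matches its true label.
#' A null (`NA`) verdict never matches, so such samples take the standard
#' loss.
#'
#' @param y true label(s) in {0, 1}.
#' @param p predicted probability(ies).
#' @param r rule verdict(s): 1, 0 or `NA`.
#' @param spec a [loss_spec()].
#' @return per-sample loss values (non-negative).
#' @export
csl <- function(y, p, r, spec = loss_spec()) {
  if (!all(y %in% c(0, 1))) stop("labels must be 0 or 1")
  p <- pmin(1 - spec$epsilon, pmax(spec$epsilon, p))
  L <- -(y * log(p) + (1 - y) * log(1 - p))
  match_ <- !is.na(r) & r == y
  ifelse(match_, (spec$alpha + 1) * L, L)
}

#' Custom total loss
#'
#' Mean of [csl()] over the sample. With `alpha = 0`, or when no verdict
#' matches its label, this equals the mean standard binary cross-entropy.
#'
#' @param y label vector.
#' @param p probability vector.
#' @param r rule-verdict vector.
#' @param spec a [loss_spec()].
#' @return a single non-negative number.
#' @export
ctl <- function(y, p, r, spec = loss_spec()) {
  n <- length(y)
  if (n < 1) stop("empty sample")
  if (length(p) != n || length(r) != n)
    stop("y, p and r must have equal length")
  mean(csl(y, p, r, spec))
}
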