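---
title: "Methods: integrating clinical knowledge across an ML pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrating clinical knowledge across an ML pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(informedml)
```

## The problem and the knowledge representation

`informedml` targets binary clinical outcome prediction on small tabular
cohorts, where purely data-driven models struggle with limited data,
missingness, and clinical acceptance. Its premise is that much of what
clinicians know about such problems can be written down in four simple
formal devices, and that each device has natural attachment points in an
ML pipeline:

1. **Intervals** (`discretisation_scheme`): each measurement is partitioned
   into ordered clinical categories (e.g. 2-hour glucose ≤ 100 mg/dL,
   101–125, ≥ 126). Intervals carry explicit closure flags on both bounds
   because published thresholds mix conventions — the diabetic glucose
   threshold is inclusive (≥ 126) while the normotensive blood-pressure
   band is exclusive (< 80).
2. **Rules** (`logic_rule`): conjunctions of threshold literals implying a
   class. The shipped base has the two public-health guideline rules for
   type-2 diabetes: severe risk at BMI ≥ 30 with glucose ≥ 126, low risk at
   BMI ≤ 25 with glucose ≤ 100. Thresholds are applied exactly as printed,
   with no epsilon; the two default antecedents are provably disjoint
   (BMI ≤ 25 vs ≥ 30).
3. **A causal DAG** (`causal_structure`): pregnancies, age, BMI and family
   history (DPF) as root causes of the outcome; the glucose and insulin
   tolerance tests as direct indicators (children of the outcome); skin
   thickness as a proxy of obesity only; blood pressure caused by both
   obesity and diabetes. Clinical knowledge names obesity and diabetes jointly as
   causative factors of hypertension, so both `BMI → BP` and
   `Outcome → BP` are shipped.
4. **Composite formulas** (`composite_formula`): linear clinical indices;
   the default is the demographic Stumvoll insulin-sensitivity estimate
   from BMI, 2-hour insulin and age.

All components reference one shared schema (`pima_schema()`): eight
features and a binary outcome. The Kaggle column dialect and the `SK`
alias for skin thickness are accepted and canonicalised on input.

Interval boundaries for glucose and BMI are anchored to the rule
thresholds. For the remaining features no textual source fixes the cuts,
so the defaults are declared provisional and overridable: blood pressure
at 80/90 mmHg (hypertension stages), 2-hour insulin at 16/166 µU/ml
(reference range), skin-fold at 10/40 mm, DPF at 0.4/0.8, and — for the
two features that needed a package-level choice — age groups at 30/45
years and pregnancies at 1/5. A knowledge base serialises to YAML or JSON
(`write_knowledge`/`read_knowledge`) and `validate_knowledge` checks
acyclicity, interval partitions, pairwise rule consistency (satisfiability
of joint antecedents where consequents conflict) and formula references.

## Missingness and imputation

Missing values are `NA` throughout; the Pima dialect's physiologically
impossible zeros in {G120, BP, ST, I120, BMI} are converted to `NA` by
`mark_implausible_zeros()`. Zero pregnancies are plausible and never
touched; a zero age contradicts the cohort definition (ages start at 21)
and is treated as a record-level violation removed by `knowledge_filter()`
rather than as missingness.

Two imputation routes are provided. Median imputation fills with
training-fold medians. Bayesian-network imputation discretises the data,
fits one CPT per node by counting with a Laplace pseudo-count (default 1: no
smoothing level is prescribed by the guidelines, and zero counts would
make exact inference brittle), and fills each missing cell with the
maximum-posterior category by exact enumeration: with 9 nodes of at most 3
categories and all four roots observed, at most 3⁵ joint states remain,
so enumeration is trivial and no approximate inference is needed. Rows
missing a root feature are excluded first (`filter_root_complete`, which
reports the retained fraction).

Posterior ties are resolved clinically: prefer the training-set median
category; otherwise the tied category ordinally closest to the median
(the "less extreme" value); at equal distance, the lower category. The
stated clinical policy covers only the first two situations; the third
step is a package extension. By default inference conditions on *all* observed
variables in the row — conditioning only on parents would discard
evidence from children — but `parents_only = TRUE` reproduces the literal
parent-based reading. Imputation statistics (medians, ranges, CPTs) are
always fitted on the training fold inside the CV harness to avoid
leakage; calling the functions with the same table on both arguments gives
whole-table fitting for replication attempts.

## Learners and the rule-weighted loss

Trees (`rpart`) and forests (`ranger`) use the case-study hyperparameters:
maximum depth 10, minimum of 5 samples to split, balanced class weights;
forests use 100 trees (not fixed by the case-study protocol; the common
default).
The neural network is a 3-layer feed-forward classifier — two ReLU hidden
layers and a sigmoid output — trained with minibatch size 20 for 24
epochs. Hidden widths (12, 8) and the Adam optimiser at learning rate
0.001 are package defaults chosen to match the small-input setting (8–10
features); all are configurable in `model_spec()` and every fit is seeded.

The learning-stage integration is the rule-weighted loss. With `r` the
per-sample tri-state rule verdict, the custom sample loss multiplies the
binary cross-entropy by (α + 1) exactly when the verdict matches the true
label; a null verdict can never match, so uncovered samples take the
standard loss — the loss definition is stated only for 0/1 verdicts, so the
null branch is fixed here explicitly. α defaults to 3 (the case-study value);
probabilities are clipped at ε = 10⁻⁷ inside the log. Because the
weighted-BCE gradient w.r.t. the output logit is simply w·(p − y), the
network trainer implements the custom loss natively rather than by sample
duplication. The trainer is written in base-R matrix code: no installed R
package exposes a per-sample-weighted BCE under this contract, and the
loss is the package's core contribution, so it is authored here and
verified against hand-derived values (0.693147, 2.772589, 1.732868) and
the α = 0 / all-null identities.

The rule-seeded tree partitions training data into rule-1 records, rule-2
records and the remainder, and grows one tree per partition; a partition
with constant labels (or an empty one) stores a constant predictor — the
seeding rule's consequent when empty. Prediction routes each record by its
verdict. With rules nothing satisfies, the construction collapses to a
single plain tree, which the tests assert prediction-identically.

## Output-stage hybrids

The rule decision unit maps verdicts to {1, 0.5, 0}. The ensemble labels a
sample diabetic iff rule score + model probability ≥ θ, default θ = 1: the
severe-risk rule then dominates the model, intermediate samples follow the
model, and a confident model (p = 1) can override the low-risk rule. The
boundary case 0.5 + 0.5 = 1.0 is classified diabetic — the formal
"1 or greater" criterion is taken as normative over the looser prose
"greater than 0.5", and this discrepancy is documented here. The output
filter discards (or, optionally, only flags) predictions that contradict
a firing rule; discarded predictions are excluded from every metric
denominator and the discard rate is reported per fold, so adherence to
the rules holds by construction on retained predictions.

## Evaluation harness

`compute_metrics` derives A, BA, P, R, F1 and MCC from confusion counts
with explicit zero-denominator conventions (precision 0 with no positive
predictions; MCC 0 on a zero denominator) and ROC-AUC by midranks
(equivalent to the normalised Mann–Whitney U, cross-checked against
`pROC` in the tests). The harness runs repeated stratified CV — default
10×10, class counts per fold within one sample of proportional — with
both pipeline variants evaluated on identical fold assignments and
identical derived fit seeds, giving the paired design the corrected test
requires. The Nadeau–Bengio statistic divides the mean per-fold difference
by √((1/k + ρ)·s²) with k − 1 degrees of freedom; ρ defaults to 1/9 for
10-fold CV but is recomputed from the actual fold sizes of the run. The
correction only inflates the variance, so the corrected |t| never exceeds
the classic paired |t|. Stars mark two-sided p below 0.1/0.05/0.01 on the
better side. Eight named strategy pairings (see `?strategies`) make the
full comparison grid a single call, and `data_efficiency()` repeats any
pairing on random subsets to probe the limited-data regime.

## The synthetic generator: what it emulates and what it does not

`sample_cohort` draws ordinal categories ancestrally from a generator
network over the causal DAG, then draws numeric values uniformly within
per-category ranges that lie strictly inside the discretisation intervals
— so generated values re-discretise to their latent categories exactly,
and integer features (pregnancies, age) are drawn as integers. Uniform
within-category draws are the simplest distribution consistent with the
interval encoding; nothing downstream depends on within-category shape.
Missingness is injected completely at random at the case-study rates
(insulin 48.7%, skin-fold 29.6%, blood pressure 4.6%, BMI 1.4%, glucose
0.7%) because no mechanism is known for the real cohort's missingness; an optional MAR mode ties
masking to the outcome for stress-testing BN against median imputation.
`rule_consistent_samples` clamps the constrained features to the
categories and sub-ranges satisfying a rule's antecedent and labels with
its consequent, for rule-aligned virtual cohorts.

The default generator CPTs are hand-set package fixtures, not estimates:
root marginals skewed toward elevated BMI, the outcome logistic in the
root ranks with intercept −3.2 — fixed once so that the exactly computed
implied prevalence is 0.350 and implied rule coverage 0.288, near the
real cohort's one-third — glucose strongly and insulin moderately shifted
by the outcome, and blood pressure interpolating toward a hypertensive
profile with BMI and outcome. The generator reproduces the qualitative
structure the pipelines assume (glucose carries more outcome information
than skin thickness; the rules fire on roughly a quarter to a third of
records) but not the real data's marginal shapes, feature correlations
beyond the DAG, or its missingness mechanism. Passing tests therefore
demonstrate correctness of the machinery and directional behaviour of the
integrations, not real-data performance levels.

A statistical note on parameter recovery: the outcome node has four
3-level parents, i.e. 81 configurations, so 50,000 samples leave ~600 per
configuration and the binomial standard error of a mid-range CPT entry
(~0.02) is as large as the recovery tolerance itself. The
parameter-recovery suite therefore uses a designated recovery network —
uniform root marginals and a near-deterministic outcome node (entries
0.01/0.99, where the standard error drops to ~0.004) — while the child
nodes keep mid-range rows that genuinely exercise the counting machinery.
Recovery of the default generator's child CPTs is additionally measured
(not asserted) by the acceptance script.

## Numerical choices and degenerate inputs

Probability clipping ε = 10⁻⁷ in the loss; CPT rows validated to sum to 1
within 10⁻⁹; posterior ties detected within 10⁻⁹; min–max scaling clips
out-of-range test values to [0, 1] and maps training-constant features to
0 with a warning; `%.17g` formatting in the CSV writer guarantees exact
numeric round-trips; constant-label training data yields constant
predictors; a zero-variance difference vector in the corrected test gives
t = 0, p = 1 (or p = 0 with a warning if the mean is nonzero); empty rule
partitions and empty tables are handled explicitly. Tree tie-breaking is
deterministic given the seed and feature order.

## Problem sizes

The test suite and acceptance script run at deliberately scaled sizes: a
768-record cohort (the real cohort's size) with 5×2-fold CV for the full
eight-strategy grid, 10⁵ random records for rule-exclusivity, 50,000
samples for parameter recovery, and 10,000 for rate-convergence checks.
These sizes keep the whole suite under a few minutes on one CPU while
leaving every statistical assertion comfortably powered; the harness runs
the full 10×10 protocol unchanged by passing `cv_config(10, 10)`.

## Known limitations

* Only conjunctive threshold rules — no disjunctions, no first-order
  constructs, no ontology ingestion.
* The DAG is always knowledge-supplied; there is no structure learning and
  no continuous (Gaussian) network variant.
* The consistency-triggered fallback-learner architecture is out of scope;
  the output stage offers the sum-threshold ensemble and the series filter.
* Synthetic cohorts validate machinery, not clinical performance; real
  cohort analyses should load the actual CSV.
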