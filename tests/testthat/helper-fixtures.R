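# Shared fixtures and independent oracles for the test suite.

make_cohort <- function(n, seed = 1, missing = FALSE) {
  cfg <- synthetic_config(
    n, missing_rates = if (missing) pima_missing_rates() else NULL,
    seed = seed)
  sample_cohort(cfg)
}

# Random feature-value records spanning the plausible ranges (for rule
# logic properties).
random_records <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    Pregnancies = sample(0:12, n, replace = TRUE),
    G120 = runif(n, 40, 250), BP = runif(n, 30, 140),
    ST = runif(n, 1, 80), I120 = runif(n, 2, 500),
    BMI = runif(n, 14, 55), DPF = runif(n, 0.05, 2.2),
    Age = sample(21:80, n, replace = TRUE)
  )
}

# Parameter-recovery generator: the default causal structure with CPTs
# designed so that every family configuration carries enough mass at
# n = 50,000 for +/-0.02 recovery (uniform roots; a near-deterministic
# outcome node, since its 81 parent configurations leave ~600 samples each,
# too few to pin mid-range probabilities; children keep mid-range rows).
recovery_bn <- function() {
  kb <- default_pima_knowledge()
  bn <- default_generator_bn(kb)
  u <- matrix(c(1, 1, 1) / 3, nrow = 1)
  for (f in c("Pregnancies", "Age", "BMI", "DPF")) bn$cpts[[f]]$prob <- u
  op <- bn$cpts$Outcome$parents
  grid <- expand.grid(lapply(bn$cpts$Outcome$parent_levels, seq_along))
  score <- rowSums(grid[, c("Age", "DPF", "Pregnancies")] - 1)
  p1 <- ifelse(score >= 4, 0.99, 0.01)
  bn$cpts$Outcome$prob <- cbind(1 - p1, p1)
  bn$cpts$G120$prob <- rbind(c(0.6, 0.3, 0.1), c(0.1, 0.3, 0.6))
  bn$cpts$I120$prob <- rbind(c(0.45, 0.4, 0.15), c(0.2, 0.4, 0.4))
  bn$cpts$ST$prob <- rbind(c(0.5, 0.4, 0.1), c(0.25, 0.5, 0.25),
                           c(0.1, 0.4, 0.5))
  bn$cpts$BP$prob <- rbind(
    c(0.85, 0.10, 0.05), c(0.10, 0.85, 0.05), c(0.05, 0.10, 0.85),
    c(0.10, 0.05, 0.85), c(0.05, 0.85, 0.10), c(0.85, 0.05, 0.10))
  fitted_bayesnet(bn$structure, bn$cpts)
}

# Brute-force metric oracle from explicit confusion counts.
oracle_metrics <- function(y, yhat) {
  tp <- sum(y == 1 & yhat == 1); fp <- sum(y == 0 & yhat == 1)
  fn <- sum(y == 1 & yhat == 0); tn <- sum(y == 0 & yhat == 0)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  spc <- if (tn + fp > 0) tn / (tn + fp) else 0
  den <- sqrt((tp + fp) * (tp + fn)) * sqrt((tn + fp) * (tn + fn))
  list(
    accuracy = (tp + tn) / length(y),
    balanced_accuracy = (rec + spc) / 2,
    precision = prec, recall = rec,
    f1 = if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0,
    mcc = if (den > 0) (tp * tn - fp * fn) / den else 0
  )
}

# Empirical mutual information between two discrete vectors (nats).
empirical_mi <- function(x, y) {
  tab <- table(x, y) / length(x)
  px <- rowSums(tab); py <- colSums(tab)
  s <- 0
  for (i in seq_along(px)) for (j in seq_along(py)) {
    if (tab[i, j] > 0) s <- s + tab[i, j] * log(tab[i, j] / (px[i] * py[j]))
  }
  s
}

pima_fixture_csv <- function(path, header = NULL, rows = NULL) {
  if (is.null(header))
    header <- c("Pregnancies", "Glucose", "BloodPressure", "SkinThickness",
                "Insulin", "BMI", "DiabetesPedigreeFunction", "Age",
                "Outcome")
  if (is.null(rows))
    rows <- c("6,148,72,35,0,33.6,0.627,50,1",
              "1,85,66,29,0,26.6,0.351,31,0",
              "8,183,64,0,0,23.3,0.672,32,1")
  writeLines(c(paste(header, collapse = ","), rows), path)
  path
}
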