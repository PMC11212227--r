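test_that("metrics match hand-derived confusion arithmetic", {
  # TP=2, FP=1, FN=1, TN=6
  y <- c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0)
  yhat <- c(1, 1, 0, 1, 0, 0, 0, 0, 0, 0)
  m <- compute_metrics(y, yhat)
  expect_equal(m$accuracy, 0.8, tolerance = 1e-4)
  expect_equal(m$precision, 0.6667, tolerance = 1e-4)
  expect_equal(m$recall, 0.6667, tolerance = 1e-4)
  expect_equal(m$f1, 0.6667, tolerance = 1e-4)
  expect_equal(m$balanced_accuracy, 0.7619, tolerance = 1e-4)
  expect_equal(m$mcc, 0.5238, tolerance = 1e-4)

  perfect <- compute_metrics(y, y, as.numeric(y))
  for (k in c("accuracy", "balanced_accuracy", "precision", "recall", "f1",
              "roc_auc"))
    expect_equal(perfect[[k]], 1)

  allneg <- compute_metrics(y, rep(0, 10))
  expect_equal(allneg$recall, 0)
  expect_equal(allneg$mcc, 0)
  expect_equal(allneg$precision, 0)
  expect_error(compute_metrics(y, yhat[1:5]), "length")
})

test_that("metrics agree with the brute-force oracle on random vectors", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(10:40, 1)
    y <- rbinom(n, 1, runif(1, 0.2, 0.8))
    yhat <- rbinom(n, 1, 0.5)
    m <- compute_metrics(y, yhat)
    o <- oracle_metrics(y, yhat)
    for (k in names(o)) expect_equal(m[[k]], o[[k]], tolerance = 1e-12)
  }
})

test_that("ROC-AUC equals the normalised Mann-Whitney U and matches pROC", {
  skip_if_not_installed("pROC")
  set.seed(41)
  for (i in 1:30) {
    n <- 60
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    scores <- round(runif(n), 2)   # duplicates exercise midranks
    auc <- compute_metrics(y, as.integer(scores >= 0.5), scores)$roc_auc
    u <- unname(wilcox.test(scores[y == 1], scores[y == 0],
                            exact = FALSE)$statistic)
    expect_equal(auc, u / (sum(y == 1) * sum(y == 0)), tolerance = 1e-12)
    expect_equal(auc,
                 as.numeric(pROC::auc(pROC::roc(
                   y, scores, quiet = TRUE, direction = "<",
                   levels = c(0, 1)))),
                 tolerance = 1e-12)
  }
})

test_that("the corrected t-test matches hand arithmetic and its limits", {
  expect_equal(nb_ttest(rep(0, 10))[c("t", "p")], list(t = 0, p = 1))
  # rho = 0 reduces to the classic paired t statistic
  set.seed(12)
  d <- rnorm(30, 0.05, 0.1)
  tt <- nb_ttest(d, rho = 0)
  classic <- t.test(d)
  expect_equal(tt$t, unname(classic$statistic), tolerance = 1e-12)
  expect_equal(tt$p, classic$p.value, tolerance = 1e-12)
  # hand-derived: k=100, mean 0.01, var 4e-4, rho 1/9
  d2 <- scale(rnorm(100))[, 1] * 0.02 + 0.01   # mean 0.01, sd 0.02 exactly
  tt2 <- nb_ttest(d2, rho = 1 / 9)
  expect_equal(tt2$t, 1.4368, tolerance = 1e-3)
  # the correction can only widen the variance
  for (rho in c(0.05, 1 / 9, 0.5)) {
    expect_lte(abs(nb_ttest(d, rho = rho)$t), abs(nb_ttest(d, rho = 0)$t))
  }
  expect_warning(res <- nb_ttest(rep(0.2, 5)), "zero variance")
  expect_equal(res$p, 0)
})

test_that("significance stars follow the 0.1 / 0.05 / 0.01 levels", {
  expect_equal(significance_stars(0.005), "***")
  expect_equal(significance_stars(0.04), "**")
  expect_equal(significance_stars(0.09), "*")
  expect_equal(significance_stars(0.5), "")
  expect_equal(significance_stars(0.01), "**")   # strict inequality
})

test_that("stratified folds partition exactly with balanced class counts", {
  set.seed(2)
  y <- rbinom(300, 1, 0.35)
  f <- stratified_folds(y, 10, seed = 5)
  expect_equal(sort(unique(f)), 1:10)
  expect_equal(length(f), 300)
  for (k in 1:10) {
    n1 <- sum(y[f == k] == 1)
    expect_lte(abs(n1 - sum(y == 1) / 10), 1)
  }
  expect_identical(stratified_folds(y, 10, seed = 5),
                   stratified_folds(y, 10, seed = 5))
  # 95 samples in 10 folds -> five folds of 10 and five of 9
  sizes <- sort(table(stratified_folds(rep(0, 95), 10, seed = 1,
                                       stratified = FALSE)))
  expect_equal(as.integer(sizes), c(rep(9, 5), rep(10, 5)))
})

majority_variant <- function() {
  pipeline_variant("majority",
    fit = function(train, seed) as.integer(mean(train$Outcome) >= 0.5),
    predict = function(state, test)
      list(prob = rep(state + 0.0, nrow(test)),
           label = rep(state, nrow(test))))
}

glucose_variant <- function() {
  pipeline_variant("glucose cut",
    fit = function(train, seed) stats::median(train$G120, na.rm = TRUE),
    predict = function(state, test) {
      p <- pmin(1, pmax(0, (test$G120 - state) / 100 + 0.5))
      list(prob = p, label = as.integer(p >= 0.5))
    })
}

test_that("the paired CV harness is exact, stratified and deterministic", {
  cohort <- make_cohort(120, seed = 8)$numeric
  cfg <- cv_config(repeats = 3, folds = 4, seed = 10)
  cv <- repeated_stratified_cv(majority_variant(), glucose_variant(),
                               cohort, cfg)
  expect_equal(nrow(cv$a), 12)
  expect_equal(nrow(cv$b), 12)
  for (r in 1:3) {
    f <- cv$assignments[r, ]
    expect_equal(sort(unique(f)), 1:4)
    expect_equal(length(f), 120)
  }
  cv2 <- repeated_stratified_cv(majority_variant(), glucose_variant(),
                                cohort, cfg)
  expect_identical(cv$assignments, cv2$assignments)
  expect_equal(cv$a, cv2$a)
  expect_equal(cv$rho, 1 / 3, tolerance = 0.01)
  # a class absent from training must error
  degenerate <- cohort
  degenerate$Outcome <- c(1, rep(0, 119))
  expect_error(repeated_stratified_cv(majority_variant(), glucose_variant(),
                                      degenerate,
                                      cv_config(repeats = 1, folds = 2)),
               "absent")
})

test_that("guideline adherence counts rule-correct samples", {
  expect_equal(
    guideline_adherence(c(1, 1, 0), c(1, 1, 1), c(1, 1, 1))$adherence,
    2 / 3, tolerance = 1e-4)
  res <- guideline_adherence(c(1, 0), c(NA, NA), c(1, 0))
  expect_true(is.na(res$adherence))
  expect_equal(res$coverage, 0)
  full <- guideline_adherence(c(1, 0, 1), c(1, 0, NA), c(1, 0, 1))
  expect_equal(full$adherence, 1.0)
  expect_equal(full$coverage, 2 / 3)
  expect_equal(full$rule_correctness, 2 / 3)
})

test_that("comparison tables carry means, stars and one row per metric", {
  cohort <- make_cohort(150, seed = 18)$numeric
  cfg <- cv_config(repeats = 2, folds = 3, seed = 4)
  cv <- repeated_stratified_cv(glucose_variant(), glucose_variant(),
                               cohort, cfg)
  cmp <- compare_cv(cv)
  expect_equal(cmp$mean_a, cmp$mean_b)
  expect_true(all(cmp$stars_a == "" & cmp$stars_b == ""))
  tab <- comparison_table(list(self = cv, again = cv))
  expect_equal(nrow(tab), 2 * 7)
  expect_setequal(unique(tab$strategy), c("self", "again"))
})

test_that("a large constant gap earns stars on the better side", {
  cohort <- make_cohort(150, seed = 19)$numeric
  noisy <- pipeline_variant("noisy",
    fit = function(train, seed) seed,
    predict = function(state, test) {
      set.seed(state)
      p <- runif(nrow(test))
      list(prob = p, label = as.integer(p >= 0.5))
    })
  cv <- repeated_stratified_cv(noisy, glucose_variant(), cohort,
                               cv_config(repeats = 3, folds = 4, seed = 2))
  cmp <- compare_cv(cv)
  acc <- cmp[cmp$metric == "accuracy", ]
  expect_gt(acc$mean_b, acc$mean_a)
  expect_true(acc$stars_b != "")
  expect_equal(acc$stars_a, "")
})

test_that("data-efficiency with the full table reproduces the plain comparison", {
  cohort <- make_cohort(100, seed = 28)$numeric
  cfg <- cv_config(repeats = 2, folds = 3, seed = 6)
  de <- data_efficiency(majority_variant(), glucose_variant(), cohort,
                        subset_size = 100, n_draws = 1, config = cfg,
                        seed = 3)
  cfg1 <- cfg; cfg1$seed <- cfg$seed + 1000L
  direct <- repeated_stratified_cv(majority_variant(), glucose_variant(),
                                   cohort, cfg1)
  expect_equal(de$draws[[1]]$a, direct$a)
  de2 <- data_efficiency(majority_variant(), glucose_variant(), cohort,
                         subset_size = 100, n_draws = 1, config = cfg,
                         seed = 3)
  expect_equal(de$summary, de2$summary)
  expect_error(data_efficiency(majority_variant(), glucose_variant(), cohort,
                               subset_size = 200, config = cfg), "subset_size")
})
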