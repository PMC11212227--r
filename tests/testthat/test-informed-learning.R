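kb <- default_pima_knowledge()

test_that("the rule vector encodes the tri-state verdicts", {
  tab <- data.frame(BMI = c(32, 22, 27), G120 = c(140, 90, 110))
  expect_equal(rule_vector(tab, kb$rules), c(1, 0, NA))
  expect_length(rule_vector(tab[0, ], kb$rules), 0)
  all_abstain <- data.frame(BMI = rep(27, 5), G120 = rep(110, 5))
  expect_true(all(is.na(rule_vector(all_abstain, kb$rules))))
})

test_that("the custom loss reproduces hand-derived values", {
  spec <- loss_spec(alpha = 3)
  expect_equal(csl(1, 0.5, NA, spec), 0.693147, tolerance = 1e-6)
  expect_equal(csl(1, 0.5, 1, spec), 2.772589, tolerance = 1e-6)
  expect_equal(csl(0, 0.5, 1, spec), 0.693147, tolerance = 1e-6)
  expect_equal(ctl(c(1, 0), c(0.5, 0.5), c(1, NA), spec), 1.732868,
               tolerance = 1e-6)
  expect_error(csl(2, 0.5, 1, spec), "0 or 1")
  expect_error(ctl(c(1, 0), 0.5, c(1, NA), spec), "length")
  expect_error(loss_spec(alpha = -1), "non-negative")
  expect_error(loss_spec(epsilon = 0.7), "epsilon")
})

test_that("the custom loss upweights and never undercuts the standard loss", {
  set.seed(14)
  for (rep in 1:20) {
    n <- 50
    y <- rbinom(n, 1, 0.4)
    p <- runif(n)
    r <- sample(c(0, 1, NA), n, replace = TRUE)
    bce <- ctl(y, p, r, loss_spec(alpha = 0))
    expect_equal(bce, mean(-(y * log(p) + (1 - y) * log(1 - p))),
                 tolerance = 1e-9)
    expect_equal(ctl(y, p, rep(NA_real_, n), loss_spec(alpha = 3)), bce,
                 tolerance = 1e-12)
    alphas <- c(0, 0.5, 1, 2, 3, 5)
    vals <- vapply(alphas, function(a) ctl(y, p, r, loss_spec(alpha = a)),
                   numeric(1))
    expect_true(all(diff(vals) >= -1e-12))   # monotone in alpha
    expect_gte(ctl(y, p, r, loss_spec(alpha = 3)), bce - 1e-12)
    any_match <- any(!is.na(r) & r == y)
    if (!any_match) expect_equal(ctl(y, p, r, loss_spec(alpha = 3)), bce)
  }
})

test_that("tree training respects depth, purity and custom-loss contracts", {
  tab <- data.frame(x = runif(50), z = runif(50))
  pure <- train_model(model_spec("decision_tree", seed = 1), tab, rep(1, 50))
  expect_equal(predict(pure, tab, type = "class"), rep(1L, 50))

  cohort <- make_cohort(700, seed = 3)$numeric
  feats <- cohort[, setdiff(names(cohort), "Outcome")]
  fit <- train_model(model_spec("decision_tree", seed = 1), feats,
                     cohort$Outcome)
  depths <- floor(log2(as.integer(rownames(fit$fit$frame))))
  expect_lte(max(depths), 10)

  expect_error(train_model(model_spec("neural_net", loss = "custom"),
                           feats, cohort$Outcome), "rule vector")
})

test_that("the network separates a linearly separable cohort", {
  set.seed(6)
  n <- 500
  tab <- data.frame(a = runif(n, 0, 100), b = runif(n, 0, 10))
  y <- as.integer(tab$a / 100 + tab$b / 10 > 1)
  fit <- train_model(model_spec("neural_net", seed = 2), tab, y)
  acc <- mean(predict(fit, tab, type = "class") == y)
  expect_gt(acc, 0.95)
  # seeded determinism
  fit2 <- train_model(model_spec("neural_net", seed = 2), tab, y)
  expect_identical(predict_prob(fit2, tab), predict_prob(fit, tab))
})

test_that("custom-loss training does not lose accuracy on rule-consistent samples", {
  deltas <- numeric(0)
  for (seed in 1:10) {
    cohort <- make_cohort(500, seed = 100 + seed)$numeric
    test <- make_cohort(500, seed = 200 + seed)$numeric
    feats <- setdiff(names(cohort), "Outcome")
    rv_tr <- rule_vector(cohort[, feats], kb$rules)
    m_std <- train_model(model_spec("neural_net", seed = seed),
                         cohort[, feats], cohort$Outcome)
    m_cus <- train_model(model_spec("neural_net", loss = "custom",
                                    alpha = 3, seed = seed),
                         cohort[, feats], cohort$Outcome, rule_vec = rv_tr)
    rv_te <- rule_vector(test[, feats], kb$rules)
    qual <- !is.na(rv_te) & rv_te == test$Outcome
    acc_std <- mean(predict(m_std, test[qual, feats], type = "class") ==
                      test$Outcome[qual])
    acc_cus <- mean(predict(m_cus, test[qual, feats], type = "class") ==
                      test$Outcome[qual])
    deltas <- c(deltas, acc_cus - acc_std)
  }
  expect_gte(mean(deltas), -0.01)
})

test_that("the rule-seeded tree partitions, routes and degenerates correctly", {
  cohort <- rbind(
    rule_consistent_samples(kb, 1, 60, seed = 1),
    rule_consistent_samples(kb, 2, 60, seed = 2))
  mid <- make_cohort(120, seed = 3)$numeric
  mid <- mid[is.na(rule_vector(mid, kb$rules)), ]
  cohort <- rbind(cohort, mid)
  feats <- setdiff(names(cohort), "Outcome")
  fit <- rule_seeded_tree_fit(cohort[, feats], cohort$Outcome, kb$rules)
  # rule-2 partition is all-healthy by construction -> constant predictor
  expect_equal(fit$submodels$rule2$type, "constant")
  expect_equal(fit$submodels$rule2$label, 0)
  rec1 <- data.frame(Pregnancies = 2, G120 = 140, BP = 70, ST = 20,
                     I120 = 120, BMI = 32, DPF = 0.5, Age = 35)
  p1 <- predict_prob(fit, rec1)
  sm <- fit$submodels$rule1
  expected <- if (sm$type == "constant") sm$label else predict_prob(sm$model, rec1)
  expect_equal(p1, expected)
  rec2 <- rec1; rec2$BMI <- 22; rec2$G120 <- 90
  expect_equal(predict_prob(fit, rec2), 0)

  # rules nothing satisfies -> identical to a plain tree
  never <- list(logic_rule(list(threshold_literal("BMI", ">=", 1000)),
                           "diabetes"),
                logic_rule(list(threshold_literal("BMI", "<=", -1000)),
                           "healthy"))
  cohort2 <- make_cohort(400, seed = 9)$numeric
  f2 <- cohort2[, feats]
  seeded <- rule_seeded_tree_fit(f2, cohort2$Outcome, never,
                                 model_spec("decision_tree", seed = 4))
  plain <- train_model(model_spec("decision_tree", seed = 4), f2,
                       cohort2$Outcome)
  expect_equal(predict_prob(seeded, f2), predict_prob(plain, f2))
})
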