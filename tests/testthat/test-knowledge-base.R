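test_that("the shipped knowledge base encodes the published guideline content", {
  kb <- default_pima_knowledge()

  r1 <- kb$rules[[1]]
  expect_equal(r1$consequent, "diabetes")
  lits <- lapply(r1$literals, function(l) c(l$feature, l$op, l$threshold))
  expect_true(list(c("BMI", ">=", "30")) %in% lits ||
                any(vapply(lits, function(x) all(x == c("BMI", ">=", "30")),
                           logical(1))))
  expect_true(any(vapply(lits, function(x)
    all(x == c("G120", ">=", "126")), logical(1))))

  r2 <- kb$rules[[2]]
  expect_equal(r2$consequent, "healthy")
  lits2 <- lapply(r2$literals, function(l) c(l$feature, l$op, l$threshold))
  expect_true(any(vapply(lits2, function(x)
    all(x == c("BMI", "<=", "25")), logical(1))))
  expect_true(any(vapply(lits2, function(x)
    all(x == c("G120", "<=", "100")), logical(1))))

  expect_setequal(structure_roots(kb$structure),
                  c("Pregnancies", "Age", "BMI", "DPF"))

  st <- kb$formulas[[1]]
  expect_equal(st$intercept, 0.222)
  expect_equal(st$coefficients[["BMI"]], -0.00333)
  expect_equal(st$coefficients[["I120"]], -0.0000779)
  expect_equal(st$coefficients[["Age"]], -0.000422)

  expect_setequal(kb$implausible_zero_features,
                  c("G120", "BP", "ST", "I120", "BMI"))
})

test_that("rule verdicts follow the guideline thresholds inclusively", {
  rules <- default_pima_knowledge()$rules
  expect_equal(rule_decision(c(BMI = 32, G120 = 140), rules), "positive")
  expect_equal(rule_decision(c(BMI = 30, G120 = 126), rules), "positive")
  expect_equal(rule_decision(c(BMI = 27, G120 = 110), rules), "abstain")
  expect_equal(rule_decision(c(BMI = 22, G120 = 90), rules), "negative")
  # just off the inclusive boundary
  expect_equal(rule_decision(c(BMI = 29.99, G120 = 126), rules), "abstain")
})

test_that("a record missing a referenced feature abstains with a warning", {
  rules <- default_pima_knowledge()$rules
  expect_warning(v <- rule_decision(c(BMI = 32), rules), "G120")
  expect_equal(v, "abstain")
})

test_that("verdicts are invariant to rule order for exclusive rules", {
  rules <- default_pima_knowledge()$rules
  recs <- random_records(200, seed = 11)
  for (i in seq_len(20)) {
    rec <- recs[i, ]
    expect_identical(suppressWarnings(rule_decision(rec, rules)),
                     suppressWarnings(rule_decision(rec, rev(rules))))
  }
})

test_that("the two default rules are mutually exclusive on random records", {
  rules <- default_pima_knowledge()$rules
  recs <- random_records(10000, seed = 3)
  r1 <- rule_vector(recs, rules[1])
  r2 <- rule_vector(recs, rules[2])
  expect_false(any(!is.na(r1) & !is.na(r2)))
})

test_that("validate_knowledge reports cycles, overlaps and unknown features", {
  kb <- default_pima_knowledge()
  expect_length(validate_knowledge(kb), 0)

  kb_cycle <- kb
  kb_cycle$structure$edges <- rbind(kb_cycle$structure$edges,
                                    data.frame(from = "Outcome", to = "BMI"))
  expect_true(any(grepl("cycle", validate_knowledge(kb_cycle))))

  # BMI <= 31 alone overlaps rule 1's BMI in [30, 31] -> conflict
  kb_conflict <- kb
  kb_conflict$rules[[2]] <- logic_rule(
    list(threshold_literal("BMI", "<=", 31)), consequent = "healthy")
  expect_true(any(grepl("conflicting", validate_knowledge(kb_conflict))))
  # but widening BMI while keeping the disjoint G120 literals stays exclusive:
  # no record can have G120 both >= 126 and <= 100
  kb_wide <- kb
  kb_wide$rules[[2]] <- logic_rule(
    list(threshold_literal("BMI", "<=", 31),
         threshold_literal("G120", "<=", 100)), consequent = "healthy")
  expect_length(validate_knowledge(kb_wide), 0)
  # overlapping antecedents with the SAME consequent are fine
  kb_dup <- kb
  kb_dup$rules[[3]] <- kb$rules[[1]]
  expect_length(validate_knowledge(kb_dup), 0)

  kb_badf <- kb
  kb_badf$formulas[[1]] <- composite_formula("x", 0, c(NotAFeature = 1))
  expect_true(any(grepl("NotAFeature", validate_knowledge(kb_badf))))
})

test_that("a knowledge base survives YAML and JSON round-trips", {
  kb <- default_pima_knowledge()
  for (ext in c("yaml", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_knowledge(kb, path)
    kb2 <- read_knowledge(path)
    expect_equal(kb_to_list(kb2), kb_to_list(kb))
    recs <- random_records(50, seed = 5)
    expect_identical(rule_vector(recs, kb2$rules),
                     rule_vector(recs, kb$rules))
    expect_identical(discretise(recs, kb2$scheme), discretise(recs, kb$scheme),
                     ignore_attr = TRUE)
  }
})
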