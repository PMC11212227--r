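kb <- default_pima_knowledge()

test_that("median imputation uses training-fold medians only", {
  tr <- data.frame(BMI = c(1, 2, NA))
  expect_equal(median_impute(tr)$BMI, c(1, 2, 1.5))
  tr2 <- data.frame(BMI = c(1, 2, 3, 4, 100))
  ap <- data.frame(BMI = NA_real_)
  expect_equal(median_impute(tr2, ap)$BMI, 3)
  clean <- data.frame(BMI = c(20, 30))
  expect_identical(median_impute(clean), clean)
  expect_error(median_impute(data.frame(BMI = NA_real_)), "BMI")
  expect_error(median_impute(data.frame(BMI = numeric(0))), "empty")
})

test_that("discretisation respects the printed inclusive boundaries", {
  tab <- data.frame(G120 = c(126, 100, 110, 125.9), BMI = c(30, 25, 27, 29.9))
  d <- discretise(tab, kb$scheme)
  expect_equal(as.character(d$G120), c("High", "Low", "Medium", "Medium"))
  expect_equal(as.character(d$BMI), c("High", "Normal", "Medium", "Medium"))
  expect_true(is.ordered(d$G120))
  # missing propagates; out-of-range errors
  dna <- discretise(data.frame(G120 = NA_real_), kb$scheme)
  expect_true(is.na(dna$G120))
  expect_error(discretise(data.frame(BMI = -3), kb$scheme), "BMI")
})

test_that("category representatives round-trip through discretisation", {
  for (f in scheme_features(kb$scheme)) {
    iv <- kb$scheme$intervals[[f]]
    rep_val <- ifelse(is.finite(iv$upper), (iv$lower + iv$upper) / 2,
                      iv$lower + 1)
    tab <- data.frame(x = rep_val); names(tab) <- f
    d <- discretise(tab, kb$scheme)
    expect_equal(as.character(d[[f]]), iv$label)
  }
})

test_that("one-hot encoding produces exactly one indicator per block", {
  tab <- data.frame(G120 = c(130, 90), BMI = c(31, 22))
  oh <- one_hot(discretise(tab, kb$scheme))
  expect_equal(ncol(oh), 6)
  expect_equal(unname(unlist(oh[1, c("G120=Low", "G120=Medium", "G120=High")])),
               c(0, 0, 1))
  expect_equal(rowSums(oh[, startsWith(names(oh), "G120=")]), c(1, 1))
  expect_equal(rowSums(oh[, startsWith(names(oh), "BMI=")]), c(1, 1))
  with_na <- discretise(data.frame(G120 = c(130, NA)), kb$scheme)
  expect_error(one_hot(with_na), "impute")
})

test_that("min-max scaling maps the training range to [0,1] and clips", {
  tr <- data.frame(x = c(0, 50, 100))
  expect_equal(minmax_scale(tr, data.frame(x = 50))$x, 0.5)
  expect_equal(minmax_scale(tr, data.frame(x = 0))$x, 0)
  expect_equal(minmax_scale(tr, data.frame(x = 120))$x, 1)
  expect_warning(out <- minmax_scale(data.frame(x = c(5, 5)),
                                     data.frame(x = c(5, 7))), "constant")
  expect_equal(out$x, c(0, 0))
})

test_that("CPT fitting matches hand counts and normalises", {
  st <- causal_structure(c("A", "B", "Outcome"),
                         rbind(c("A", "B"), c("A", "Outcome")))
  scheme <- discretisation_scheme(list(
    A = rbind(data.frame(label = "Low", lower = 0, upper = 1,
                         lower_closed = TRUE, upper_closed = TRUE),
              data.frame(label = "High", lower = 1, upper = 2,
                         lower_closed = FALSE, upper_closed = TRUE)),
    B = rbind(data.frame(label = "Low", lower = 0, upper = 1,
                         lower_closed = TRUE, upper_closed = TRUE),
              data.frame(label = "High", lower = 1, upper = 2,
                         lower_closed = FALSE, upper_closed = TRUE))))
  tab <- data.frame(
    A = factor(c("Low", "Low", "Low", "Low", "High"),
               levels = c("Low", "High"), ordered = TRUE),
    B = factor(c("Low", "Low", "Low", "High", "High"),
               levels = c("Low", "High"), ordered = TRUE),
    Outcome = factor(c(0, 0, 1, 1, 1), levels = c(0, 1)))
  bn0 <- fit_cpts(tab, st, smoothing = 0, scheme = scheme)
  expect_equal(bn0$cpts$B$prob[1, ], c(0.75, 0.25))   # counts 3:1 given A=Low
  bn1 <- fit_cpts(tab, st, smoothing = 1, scheme = scheme)
  # never-observed parent configurations go uniform under Laplace smoothing
  tab2 <- tab[tab$A == "Low", ]
  bn2 <- fit_cpts(tab2, st, smoothing = 1, scheme = scheme)
  expect_equal(bn2$cpts$B$prob[2, ], c(0.5, 0.5))
  for (n in names(bn1$cpts))
    expect_equal(rowSums(bn1$cpts[[n]]$prob), rep(1, nrow(bn1$cpts[[n]]$prob)),
                 tolerance = 1e-9)
  expect_error(fit_cpts(tab[0, ], st, scheme = scheme), "empty")
})

test_that("imputation picks the maximum-posterior category", {
  bn <- default_generator_bn()
  cohort <- make_cohort(400, seed = 21)
  cat_tab <- cohort$categories
  med <- median_categories(cat_tab[, setdiff(names(cat_tab), "Outcome")])
  masked <- cat_tab
  masked$G120[1:50] <- NA
  imp <- bn_impute(masked, bn, med)
  expect_false(anyNA(imp$G120))
  # with a unique argmax the filled category maximises the exact posterior
  for (i in 1:5) {
    o <- cat_tab$Outcome[i]
    post <- bn$cpts$G120$prob[o + 1, ]  # G120 depends only on Outcome, which
    # is observed, and G120 has no children: posterior = CPT row
    expect_equal(as.character(imp$G120[i]),
                 bn$cpts$G120$levels[which.max(post)])
  }
})

test_that("posterior ties resolve to the median, then the less extreme category", {
  st <- causal_structure(c("A", "B", "Outcome"),
                         rbind(c("A", "B"), c("A", "Outcome")))
  lv3 <- c("Low", "Medium", "High")
  cpts <- list(
    A = list(parents = character(0), levels = lv3, parent_levels = list(),
             prob = matrix(c(1 / 3, 1 / 3, 1 / 3), nrow = 1)),
    B = list(parents = "A", levels = lv3,
             parent_levels = list(A = lv3),
             prob = rbind(c(0.10, 0.45, 0.45),    # tie Medium/High
                          c(0.45, 0.10, 0.45),    # tie Low/High
                          c(0.45, 0.45, 0.10))),  # tie Low/Medium
    Outcome = list(parents = "A", levels = c("0", "1"),
                   parent_levels = list(A = lv3),
                   prob = rbind(c(0.5, 0.5), c(0.5, 0.5), c(0.5, 0.5))))
  bn <- fitted_bayesnet(st, cpts)
  tab <- data.frame(
    A = factor(c("Low", "Medium", "High"), levels = lv3, ordered = TRUE),
    B = factor(c(NA, NA, NA), levels = lv3, ordered = TRUE),
    Outcome = c(0, 0, 0))
  imp <- bn_impute(tab, bn, train_medians = c(B = "Medium"))
  # tie {Medium, High}, median Medium -> Medium
  expect_equal(as.character(imp$B[1]), "Medium")
  # tie {Low, High}, median Medium: equal ordinal distance -> lower (Low)
  expect_equal(as.character(imp$B[2]), "Low")
  # tie {Low, Medium}, median Medium -> Medium
  expect_equal(as.character(imp$B[3]), "Medium")
})

test_that("imputation never alters observed cells and errors on missing roots", {
  bn <- default_generator_bn()
  cohort <- make_cohort(300, seed = 33)
  cat_tab <- cohort$categories
  feats <- setdiff(names(cat_tab), "Outcome")
  med <- median_categories(cat_tab[, feats])
  set.seed(5)
  masked <- cat_tab
  for (f in c("G120", "I120", "ST", "BP")) {
    masked[[f]][sample.int(300, 60)] <- NA
  }
  imp <- bn_impute(masked, bn, med)
  for (f in feats) {
    obs <- !is.na(masked[[f]])
    expect_identical(imp[[f]][obs], masked[[f]][obs])
  }
  expect_false(anyNA(imp[, feats]))
  bad <- masked
  bad$BMI[3] <- NA
  expect_error(bn_impute(bad, bn, med), "root")
})

test_that("refitted CPTs recover the generator within binomial tolerance", {
  bn <- recovery_bn()
  cfg <- synthetic_config(20000, bn = bn, seed = 77)
  s <- sample_cohort(cfg)
  cat_tab <- s$categories
  cat_tab$Outcome <- factor(cat_tab$Outcome, levels = c(0, 1))
  fit <- fit_cpts(cat_tab, bn$structure, smoothing = 1,
                  scheme = default_pima_scheme())
  for (n in c("G120", "I120", "ST", "BP")) {
    expect_lt(max(abs(fit$cpts[[n]]$prob - bn$cpts[[n]]$prob)), 0.03)
  }
})

test_that("root-complete filtering reports the retained fraction", {
  cohort <- make_cohort(10, seed = 2)$numeric
  full <- filter_root_complete(cohort, kb$structure)
  expect_equal(nrow(full), 10)
  expect_equal(attr(full, "retained_fraction"), 1.0)
  cohort$BMI[4] <- NA
  sub <- filter_root_complete(cohort, kb$structure)
  expect_equal(nrow(sub), 9)
  expect_equal(attr(sub, "retained_fraction"), 0.9)
  # missingness in a non-root feature does not drop rows
  cohort$I120[2] <- NA
  expect_equal(nrow(filter_root_complete(cohort, kb$structure)), 9)
})

test_that("knowledge filtering removes implausible records and itemises them", {
  cohort <- make_cohort(20, seed = 4)$numeric
  clean <- knowledge_filter(cohort, kb)
  expect_equal(nrow(clean$table), 20)
  expect_equal(nrow(clean$report), 0)
  cohort$Age[3] <- 0
  cohort$BMI[7] <- -3
  res <- knowledge_filter(cohort, kb)
  expect_equal(nrow(res$table), 18)
  expect_setequal(res$report$feature, c("Age", "BMI"))
  expect_true(all(c(3, 7) %in% res$report$row))
})

test_that("imputation and filtering respect row-count invariants", {
  cohort <- make_cohort(120, seed = 13, missing = TRUE)$numeric
  expect_equal(nrow(median_impute(cohort)), 120)
  expect_lte(nrow(filter_root_complete(cohort, kb$structure)), 120)
  expect_lte(nrow(knowledge_filter(cohort, kb)$table), 120)
})
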