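test_that("cross-tabulation lays out both models correctly", {
  lab <- reference_study_labels()
  m1 <- crosstab(lab$predictor, lab$truth)
  expect_equal(unname(m1["neglect", ]), c(7, 1, 1))
  expect_equal(unname(m1["non_neglect", ]), c(6, 28, 8))
  expect_equal(unname(m1["minor_atypicality", ]), c(0, 0, 0))

  m2 <- crosstab(lab$predictor, lab$truth, merge_minor = TRUE)
  expect_equal(unname(m2["neglect", ]), c(7, 2))
  expect_equal(unname(m2["non_neglect", ]), c(6, 36))

  expect_error(crosstab(character(), character()), "nonempty")
  expect_error(crosstab("maybe", "neglect"), "unknown predictor")
  expect_error(crosstab("neglect", "sometimes"), "unknown truth")
  # logical and 0/1 predictors are accepted
  expect_equal(
    crosstab(c(1, 0), c("neglect", "non_neglect"))["neglect", "neglect"], 1L
  )
})

test_that("per-class metrics handle perfection and undefined denominators", {
  perfect <- crosstab(
    rep(c("neglect", "non_neglect"), c(5, 5)),
    rep(c("neglect", "non_neglect"), c(5, 5)),
    merge_minor = TRUE
  )
  m <- class_metrics(perfect, "neglect")
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  expect_equal(m$balanced_accuracy, 1)
  expect_equal(m$ppv, 1)
  expect_equal(m$f1, 1)

  # a never-predicted class has undefined PPV and F1, not zero
  lab <- reference_study_labels()
  m1 <- crosstab(lab$predictor, lab$truth)
  minor <- class_metrics(m1, "minor_atypicality")
  expect_equal(minor$sensitivity, 0)
  expect_equal(minor$specificity, 1)
  expect_true(is.na(minor$ppv))
  expect_true(is.na(minor$f1))
  expect_equal(minor$npv, 42 / 51)
})

test_that("PPV/NPV via prevalence equal the direct cell forms", {
  set.seed(5)
  for (i in 1:25) {
    truth <- sample(c("neglect", "non_neglect"), 40, replace = TRUE)
    pred <- ifelse(stats::runif(40) < 0.7, truth,
      sample(c("neglect", "non_neglect"), 40, replace = TRUE)
    )
    m <- crosstab(pred, truth, merge_minor = TRUE)
    met <- class_metrics(m, "neglect")
    tp <- m["neglect", "neglect"]
    fp <- m["neglect", "non_neglect"]
    fn <- m["non_neglect", "neglect"]
    tn <- m["non_neglect", "non_neglect"]
    if (tp + fp > 0) expect_equal(met$ppv, tp / (tp + fp))
    if (tn + fn > 0) expect_equal(met$npv, tn / (tn + fn))
    expect_equal(met$balanced_accuracy, (met$sensitivity + met$specificity) / 2)
  }
})

test_that("exact accuracy interval contains the estimate and respects [0,1]", {
  full <- crosstab(rep("neglect", 5), rep("neglect", 5), merge_minor = TRUE)
  acc <- overall_accuracy(full)
  expect_equal(acc$accuracy, 1)
  expect_equal(acc$ci_high, 1)
  set.seed(6)
  for (i in 1:20) {
    n <- sample(5:60, 1)
    truth <- sample(c("neglect", "non_neglect"), n, replace = TRUE)
    pred <- sample(c("neglect", "non_neglect"), n, replace = TRUE)
    a <- overall_accuracy(crosstab(pred, truth, merge_minor = TRUE))
    expect_true(a$ci_low >= 0 && a$ci_high <= 1)
    expect_true(a$ci_low <= a$accuracy && a$accuracy <= a$ci_high)
  }
})

test_that("null accuracy is the most prevalent truth class", {
  expect_equal(
    null_accuracy(rep(c("neglect", "non_neglect", "minor_atypicality"), c(13, 29, 9))),
    29 / 51
  )
  expect_equal(null_accuracy(rep("neglect", 4)), 1)
})

test_that("the null-accuracy test is a one-sided exact binomial tail", {
  # observing exactly the null expectation cannot be significant
  expect_gte(accuracy_vs_null_test(25, 50, 0.5), 0.5)
  expect_equal(
    accuracy_vs_null_test(40, 50, 0.5),
    sum(stats::dbinom(40:50, 50, 0.5))
  )
})

test_that("kappa is 1 at identity, 0 for a constant predictor", {
  ident <- matrix(c(5, 0, 0, 5), 2,
    dimnames = list(
      c("neglect", "non_neglect"), c("neglect", "non_neglect")
    )
  )
  expect_equal(cohen_kappa(ident), 1)
  const <- crosstab(
    rep("non_neglect", 20),
    rep(c("neglect", "non_neglect"), 10),
    merge_minor = TRUE
  )
  expect_equal(cohen_kappa(const), 0)
  # all agreement by construction -> chance agreement 1 -> undefined
  degenerate <- crosstab(rep("neglect", 4), rep("neglect", 4), merge_minor = TRUE)
  expect_true(is.na(cohen_kappa(degenerate)))
})

test_that("binary-predictor Poisson IRR equals the ratio of group means", {
  d <- tibble::tibble(
    atypicality = c(rep(2, 10), rep(0, 5), rep(1, 5)), # means: yes 2.0, no 0.5
    x = rep(c("yes", "no"), c(10, 10))
  )
  fit <- poisson_risk(d, "atypicality", "x")
  expect_equal(fit$irr, 2.0 / 0.5, tolerance = 1e-8)
  expect_equal(fit$reference, "no") # least frequent tie resolved by order
  expect_true(fit$ci_low <= fit$irr && fit$irr <= fit$ci_high)
})

test_that("an unrelated predictor gives IRR near 1 with nominal CI coverage", {
  set.seed(12)
  covered <- logical(10)
  for (i in 1:10) {
    d <- tibble::tibble(
      atypicality = stats::rpois(400, 1.5),
      x = sample(c("a", "b"), 400, replace = TRUE)
    )
    fit <- poisson_risk(d, "atypicality", "x")
    expect_lt(abs(log(fit$irr)), 0.5)
    covered[i] <- fit$ci_low < 1 && fit$ci_high > 1
  }
  expect_gte(sum(covered), 8) # 95% nominal coverage
})

test_that("categorical predictors use the least frequent reference", {
  set.seed(13)
  d <- tibble::tibble(
    atypicality = stats::rpois(60, 1),
    x = rep(c("common", "mid", "rare"), c(40, 15, 5))
  )
  fit <- poisson_risk(d, "atypicality", "x")
  expect_true(all(fit$reference == "rare"))
  expect_setequal(fit$level, c("common", "mid"))
  fit2 <- poisson_risk(d, "atypicality", "x", combine_two_least = TRUE)
  expect_equal(unique(fit2$reference), "mid+rare") # combined, sorted label
  expect_error(
    poisson_risk(tibble::tibble(atypicality = 1:3, x = "a"), "atypicality", "x"),
    "distinct"
  )
})

test_that("confusion_analysis bundles both models with tidy/glance access", {
  lab <- reference_study_labels()
  conf <- confusion_analysis(lab$predictor, lab$truth)
  g <- glance(conf)
  expect_equal(g$n, 51)
  expect_equal(g$model1_accuracy, 35 / 51)
  expect_equal(g$model2_accuracy, 43 / 51)
  td <- tidy(conf)
  expect_setequal(td$class, c("neglect", "non_neglect", "minor_atypicality"))
})
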