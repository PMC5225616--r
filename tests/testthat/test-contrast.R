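test_that("loss arithmetic and rounding reproduce the reporting convention", {
  r <- qaly_loss(12.7, 4.4)
  expect_equal(round(r$loss, 1), 8.3)
  expect_equal(round(r$percent_loss), 65)
  r <- qaly_loss(14.0, 7.8)
  expect_equal(round(r$loss, 1), 6.2)
  expect_equal(round(r$percent_loss), 44)
  r <- qaly_loss(3, 3)
  expect_equal(r$loss, 0)
  expect_equal(r$percent_loss, 0)
  expect_error(qaly_loss(0, 1), "positive")
  # percent loss is invariant to common rescaling
  expect_equal(qaly_loss(12.7, 4.4)$percent_loss,
               qaly_loss(12.7 * 3.7, 4.4 * 3.7)$percent_loss)
})

test_that("propensity model recovers a known logistic exposure law", {
  set.seed(55)
  n <- 20000
  age <- runif(n, 65, 90)
  sex <- sample(c("male", "female"), n, replace = TRUE)
  lp <- -8 + 0.09 * age + 0.4 * (sex == "female")
  exposed <- runif(n) < plogis(lp)
  cohort <- data.frame(age = age, sex = sex, weight = 1)
  ps <- estimate_propensity(cohort, exposed)
  cf <- coef(ps$model)
  expect_equal(unname(cf["age"]), 0.09, tolerance = 0.1)
  expect_equal(unname(cf["sexmale"]), -0.4, tolerance = 0.25)
  expect_true(all(ps$scores > 0 & ps$scores < 1))
})

test_that("constant covariates give intercept-only scores at the exposed fraction", {
  cohort <- data.frame(age = rep(70, 200), sex = "female", weight = 1)
  exposed <- rep(c(TRUE, FALSE), c(60, 140))
  ps <- estimate_propensity(cohort, exposed)
  expect_equal(ps$scores, rep(0.3, 200), tolerance = 1e-9)
  # stabilization: constant scores reduce balance weights to the base weights
  bw <- balance_weights(ps$scores, exposed, base_weights = rep(2, 200))
  expect_equal(bw, rep(2, 200), tolerance = 1e-9)
})

test_that("stabilized weights average to about one per group and trim extremes", {
  set.seed(56)
  n <- 5000
  age <- runif(n, 65, 90)
  exposed <- runif(n) < plogis(-15 + 0.2 * age)
  cohort <- data.frame(age = age, sex = "female", weight = runif(n, 0.5, 2))
  ps <- estimate_propensity(cohort, exposed, covariates = "age")
  bw <- balance_weights(ps$scores, exposed, cohort$weight)
  sw <- bw / cohort$weight
  expect_equal(mean(sw[exposed]), 1, tolerance = 0.15)
  expect_equal(mean(sw[!exposed]), 1, tolerance = 0.15)
  expect_warning(balance_weights(c(1e-9, 0.5), c(TRUE, FALSE), c(1, 1)),
                 "trimmed")
})

test_that("weighting shrinks the age imbalance on a confounded cohort", {
  coh <- generate_cohort(cohort_spec(n = 12000, seed = 14,
                                     age_severity_shift = 4))
  exposed <- coh$severity %in% c("moderate", "modsev_severe")
  ps <- estimate_propensity(coh, exposed)
  bw <- balance_weights(ps$scores, exposed, coh$weight)
  raw_gap <- abs(weighted.mean(coh$age[exposed], coh$weight[exposed]) -
                   weighted.mean(coh$age[!exposed], coh$weight[!exposed]))
  adj_gap <- abs(weighted.mean(coh$age[exposed], bw[exposed]) -
                   weighted.mean(coh$age[!exposed], bw[!exposed]))
  expect_lt(adj_gap, raw_gap / 3)
})

test_that("contrasts with identical laws are null and deterministic", {
  # mild shares none_minimal's utility and mortality laws: expected loss 0
  spec <- cohort_spec(
    n = 4000, seed = 8,
    category_prevalence = c(none_minimal = 0.5, mild = 0.5, moderate = 0,
                            modsev_severe = 0),
    utility_mean = c(none_minimal = 0.8, mild = 0.8, moderate = 0.5,
                     modsev_severe = 0.4),
    weibull_scale = c(none_minimal = 14, mild = 14, moderate = 10,
                      modsev_severe = 9),
    weibull_shape = c(none_minimal = 1.4, mild = 1.4, moderate = 1.4,
                      modsev_severe = 1.4))
  coh <- generate_cohort(spec)
  ct <- contrast_spec("null_mild", "mild", "none_minimal")
  r1 <- run_contrast(coh, ct, boot = 50, boot_seed = 2)
  r2 <- run_contrast(coh, ct, boot = 50, boot_seed = 2)
  expect_identical(r1$loss, r2$loss)
  expect_identical(r1$se_loss, r2$se_loss)
  expect_lt(abs(r1$loss), 2 * r1$se_loss)
})

test_that("default-spec MDD contrast recovers the analytic truth difference", {
  spec <- cohort_spec(n = 20000, seed = 18)
  coh <- generate_cohort(spec)
  res <- run_contrast(coh, standard_contrasts()[[1]])  # mdd vs no mdd
  p <- spec$category_prevalence
  truth_ref <- sum(p[c("none_minimal", "mild")] / sum(p[c("none_minimal", "mild")]) *
                     c(true_group_qaly(spec, "none_minimal"),
                       true_group_qaly(spec, "mild")))
  truth_exp <- sum(p[c("moderate", "modsev_severe")] /
                     sum(p[c("moderate", "modsev_severe")]) *
                     c(true_group_qaly(spec, "moderate"),
                       true_group_qaly(spec, "modsev_severe")))
  expect_equal(res$loss, truth_ref - truth_exp, tolerance = 0.12)
})

test_that("weighted and unweighted contrasts agree when weights are uninformative", {
  coh <- generate_cohort(cohort_spec(n = 15000, seed = 19))
  ct <- contrast_spec("mild_v_none", "mild", "none_minimal")
  rw <- run_contrast(coh, ct)
  coh$weight <- 1
  ru <- run_contrast(coh, ct)
  expect_equal(rw$loss, ru$loss, tolerance = 0.35)
})

test_that("groups too small for the Weibull fit are flagged, not dropped", {
  coh <- generate_cohort(cohort_spec(n = 400, seed = 23,
    category_prevalence = c(none_minimal = 0.995, mild = 0.005, moderate = 0,
                            modsev_severe = 0)))
  # force the tiny group to have <2 distinct events
  coh$event[coh$severity == "mild"] <- 0L
  res <- run_contrast(coh, contrast_spec("tiny", "mild", "none_minimal"))
  expect_true(isTRUE(res$unestimable))
  expect_match(res$reason, "event times|survivors|nonempty")
})
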