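test_that("default spec carries the calibrated prevalence/utility gradients", {
  spec <- cohort_spec()
  expect_equal(unname(spec$category_prevalence["none_minimal"]), 0.821)
  expect_equal(unname(spec$utility_mean["mild"]), 0.680)
  expect_equal(sum(spec$category_prevalence), 1, tolerance = 1e-12)
  expect_true(all(diff(spec$utility_mean) < 0))
  # mean lifetimes implied by scale * Gamma(1 + 1/shape) decrease with severity
  le <- spec$weibull_scale * gamma(1 + 1 / spec$weibull_shape)
  expect_true(all(diff(le) < 0))
})

test_that("invalid specs are rejected at construction", {
  expect_error(cohort_spec(category_prevalence = c(none_minimal = 0.9,
                                                   mild = 0.2, moderate = 0,
                                                   modsev_severe = 0)),
               "sum to 1")
  expect_error(cohort_spec(weibull_shape = c(none_minimal = -1, mild = 1,
                                             moderate = 1, modsev_severe = 1)),
               "positive")
  expect_error(cohort_spec(followup_window = c(5, 2)), "min <= max")
  expect_error(cohort_spec(utility_mean = c(none_minimal = 1.2, mild = 0.5,
                                            moderate = 0.4,
                                            modsev_severe = 0.3)),
               "strictly between")
})

test_that("analytic group QALY matches closed forms and quadrature", {
  spec <- cohort_spec(utility_mean = c(none_minimal = 1 - 1e-9, mild = 0.5,
                                       moderate = 0.4, modsev_severe = 0.3),
                      weibull_scale = c(none_minimal = 10, mild = 10,
                                        moderate = 16, modsev_severe = 5),
                      weibull_shape = c(none_minimal = 1, mild = 1,
                                        moderate = 1.3, modsev_severe = 2))
  expect_equal(true_group_qaly(spec, "none_minimal"), 10, tolerance = 1e-6)
  expect_equal(true_group_qaly(spec, "mild"), 5, tolerance = 1e-9)
  expect_equal(true_group_qaly(spec, "moderate"),
               0.4 * quadrature_weibull_mean(16, 1.3), tolerance = 1e-9)
  expect_error(true_group_qaly(spec, "severe"), "unknown category")
})

test_that("generation is deterministic, schema-complete, and leaves the RNG alone", {
  spec <- cohort_spec(n = 300, seed = 77)
  set.seed(1); before <- runif(1)
  set.seed(1)
  c1 <- generate_cohort(spec)
  after <- runif(1)
  expect_identical(before, after)   # caller's stream untouched
  c2 <- generate_cohort(spec)
  expect_identical(c1, c2)
  expect_true(all(c("id", "age", "sex", "weight", "phq1", "phq9", "phq_total",
                    "genhlth", "physdays", "mentdays", "actdays", "eq5d",
                    "n_comorbid", "income_fpl_ratio", "education", "married",
                    "time", "event", "severity") %in% names(c1)))
  empty <- generate_cohort(cohort_spec(n = 0))
  expect_identical(nrow(empty), 0L)
  expect_true(all(names(c1) %in% names(empty)))
})

test_that("every row satisfies the censoring bookkeeping and score consistency", {
  coh <- generate_cohort(cohort_spec(n = 5000, seed = 5))
  expect_true(all(coh$time > 0))
  expect_true(all(coh$time <= coh$true_death_time))
  # deaths are observed exactly at the latent death time, censored rows earlier
  expect_true(all((coh$event == 1L) == (coh$time == coh$true_death_time)))
  # administrative censoring stays inside the follow-up window
  expect_true(all(coh$time[coh$event == 0L] >= 1.5 - 1e-12))
  expect_true(all(coh$time[coh$event == 0L] <= 6.5 + 1e-12))
  # item sums equal totals, and totals sit inside the assigned category range
  items <- as.matrix(coh[, paste0("phq", 1:9)])
  expect_true(all(rowSums(items) == coh$phq_total))
  expect_identical(categorize_phq9(coh$phq_total, collapsed = TRUE),
                   coh$severity)
  expect_true(all(coh$eq5d >= 0 & coh$eq5d <= 1))
  expect_true(all(coh$weight > 0))
})

test_that("PHQ-9 item vectors are uniform over compositions of the total", {
  # total = 2 over 9 items in {0..3}: 45 compositions, 9 of them use a single
  # item of 2; P(single 2) = 9/45 = 0.2
  spec <- cohort_spec(n = 8000, seed = 13,
                      category_prevalence = c(none_minimal = 1, mild = 0,
                                              moderate = 0, modsev_severe = 0))
  coh <- generate_cohort(spec)
  sub <- coh[coh$phq_total == 2L, paste0("phq", 1:9)]
  has_two <- apply(sub, 1, function(x) any(x == 2))
  expect_equal(mean(has_two), 0.2, tolerance = 0.05)
})

test_that("large cohorts track prevalences, utility ordering, mortality gradient", {
  spec <- cohort_spec(n = 100000, seed = 1)
  coh <- generate_cohort(spec)
  shares <- table(coh$severity) / nrow(coh)
  expect_true(all(abs(shares - spec$category_prevalence) < 0.01))
  by_cat <- split(coh, coh$severity)
  u_means <- vapply(by_cat, function(g) mean(g$eq5d), numeric(1))
  expect_true(all(diff(u_means) < 0))
  rates <- vapply(by_cat, function(g) sum(g$event) / sum(g$time), numeric(1))
  expect_true(all(diff(rates) > 0))
})

test_that("stress switches change the intended couplings", {
  base <- cohort_spec(n = 6000, seed = 3)
  conf <- cohort_spec(n = 6000, seed = 3, age_severity_shift = 4)
  c1 <- generate_cohort(base); c2 <- generate_cohort(conf)
  mean_age <- function(coh) tapply(coh$age, coh$severity, mean)
  expect_lt(diff(range(mean_age(c1))), 2)
  expect_gt(mean_age(c2)["modsev_severe"] - mean_age(c2)["none_minimal"], 6)
  inf <- generate_cohort(cohort_spec(n = 6000, seed = 3,
                                     informative_weights = TRUE))
  w_by <- tapply(inf$weight, inf$severity, mean)
  expect_gt(w_by["modsev_severe"] / w_by["none_minimal"], 1.5)
  ltfu <- generate_cohort(cohort_spec(n = 6000, seed = 3, ltfu_rate = 0.3))
  expect_lt(mean(ltfu$time), mean(c1$time))
})
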