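test_that("descriptive summaries use n, min, max, mean and sample SD", {
  two <- rbind(
    participant_record(40, 65, 1.70, 5, "individual", 3, 2, 40, FALSE),
    participant_record(44, 65, 1.70, 5, "individual", 3, 2, 40, FALSE)
  )
  s <- summarize_cohort(two)
  age <- s$numeric[s$numeric$variable == "age", ]
  expect_equal(age$n, 2L)
  expect_equal(age$mean, 42)
  expect_equal(age$sd, sqrt(8), tolerance = 1e-12)  # 2.828427
  expect_equal(c(age$min, age$max), c(40, 44))
})

test_that("a cohort of identical records has zero SD everywhere", {
  s <- summarize_cohort(homogeneous_cohort(5))
  num <- s$numeric[s$numeric$n > 1, ]
  expect_true(all(num$sd == 0))
  # categorical proportions sum to 1 within each variable
  props <- tapply(s$categorical$proportion, s$categorical$variable, sum)
  expect_true(all(abs(props - 1) < 1e-12))
})

test_that("conditional variables are summarized over extra trainers only", {
  cohort <- fixture_cohort()
  s <- summarize_cohort(cohort)
  num <- s$numeric
  expect_equal(num$n[num$variable == "prep_weeks"], 3L)
  expect_equal(num$n[num$variable == "age"], 6L)
})

test_that("summaries are invariant under record order", {
  cohort <- generate_cohort(synthetic_cohort_params(n = 200, seed = 3))
  s1 <- summarize_cohort(cohort)
  s2 <- summarize_cohort(cohort[sample.int(200), ])
  expect_equal(s1$numeric, s2$numeric)
  expect_equal(s1$categorical, s2$categorical)
})

test_that("the Welch t-test matches an independent reference", {
  # scipy.stats.ttest_ind([1,2,3], [1,2,3,4,5,6], equal_var=False)
  fit <- welch_t_test(c(1, 2, 3), c(1, 2, 3, 4, 5, 6))
  expect_equal(fit$statistic, -1.566698903601, tolerance = 1e-10)
  expect_equal(fit$p_value, 0.162434787442, tolerance = 1e-10)
  expect_equal(fit$df, 6.797752808989, tolerance = 1e-10)
})

test_that("Welch t on identical samples is null; shifts grow |t|", {
  x <- c(3, 5, 8, 13)
  same <- welch_t_test(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  shifts <- sapply(c(0.5, 1, 2, 4), function(d) {
    abs(welch_t_test(x, x + d)$statistic)
  })
  expect_true(all(diff(shifts) > 0))
  expect_error(welch_t_test(1, c(1, 2)), "at least 2")
  expect_error(welch_t_test(c(2, 2), c(3, 3)), "zero variance")
})

test_that("the chi-square test matches the hand Pearson formula", {
  # [[10,20],[20,10]]: all expected counts 15, statistic 4 * 25/15
  fit <- chi_square_test(matrix(c(10, 20, 20, 10), 2, byrow = TRUE))
  expect_equal(fit$statistic, 20 / 3, tolerance = 1e-12)
  expect_equal(fit$df, 1)
  expect_equal(fit$p_value, 0.009823274508, tolerance = 1e-10)
})

test_that("chi-square: independence gives 0, permutations leave it fixed", {
  ident <- matrix(c(5, 10, 5, 10), 2, byrow = TRUE)
  fit <- chi_square_test(ident)
  expect_equal(fit$statistic, 0)
  expect_equal(fit$p_value, 1)
  tab <- matrix(c(12, 7, 3, 9, 14, 6), 2, byrow = TRUE)
  base <- chi_square_test(tab)$statistic
  expect_equal(chi_square_test(tab[2:1, ])$statistic, base)
  expect_equal(chi_square_test(tab[, c(2, 3, 1)])$statistic, base)
  expect_equal(chi_square_test(t(tab))$statistic, base)
  expect_error(chi_square_test(matrix(c(0, 0, 3, 4), 2)), "degenerate")
})

test_that("2x2 odds ratios follow the cross-product rule", {
  expect_equal(odds_ratio_2x2(10, 10, 10, 10)$or, 1)
  fit <- odds_ratio_2x2(30, 70, 15, 85)
  expect_equal(fit$or, (30 * 85) / (70 * 15), tolerance = 1e-12)  # 2.4286
  expect_equal(fit$se_log_or, sqrt(1 / 30 + 1 / 70 + 1 / 15 + 1 / 85),
               tolerance = 1e-12)
  # CI contains the estimate; swapping rows inverts the OR
  expect_true(fit$ci[1] < fit$or && fit$or < fit$ci[2])
  expect_equal(odds_ratio_2x2(15, 85, 30, 70)$or, 1 / fit$or,
               tolerance = 1e-12)
})

test_that("zero cells trigger the Haldane-Anscombe correction", {
  fit <- odds_ratio_2x2(0, 10, 5, 5)
  expect_true(fit$haldane_corrected)
  expect_equal(fit$or, (0.5 * 5.5) / (10.5 * 5.5), tolerance = 1e-12)
  expect_false(odds_ratio_2x2(1, 10, 5, 5)$haldane_corrected)
  expect_error(odds_ratio_2x2(0, 0, 5, 5), "zero row or column margin")
})

test_that("logistic regression with one binary predictor reproduces the
           cross-product OR over a sweep of small tables", {
  cells <- c(1, 3, 7, 19)
  grid <- expand.grid(a = cells, b = cells, c = cells, d = cells)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    y <- rep(c(1, 0, 1, 0), times = c(g$a, g$b, g$c, g$d))
    x <- rep(c(1, 1, 0, 0), times = c(g$a, g$b, g$c, g$d))
    fit <- logistic_fit(y, data.frame(x = x))
    or_glm <- fit$coefficients$or[fit$coefficients$term == "x"]
    or_tab <- (g$a * g$d) / (g$b * g$c)
    expect_equal(or_glm, or_tab, tolerance = 1e-6)
  }
})

test_that("logistic slope is null when the outcome ignores the predictor", {
  set.seed(4)
  y <- rbinom(4000, 1, 0.4)
  x <- rbinom(4000, 1, 0.5)
  fit <- logistic_fit(y, data.frame(x = x))
  slope <- fit$coefficients[fit$coefficients$term == "x", ]
  expect_lt(abs(slope$estimate), 3 * slope$se)
})

test_that("logistic regression reports separation and bad inputs", {
  y <- c(0, 0, 0, 1, 1, 1)
  x <- c(0, 0, 0, 1, 1, 1)
  expect_error(logistic_fit(y, data.frame(x = x)), "separation|converge")
  expect_error(logistic_fit(c(0, 1, 2), data.frame(x = 1:3)), "binary")
})

test_that("the improved-health model recovers an injected OR of 2.49", {
  # 5,000 extra trainers with the association injected at the 450-min split
  p <- synthetic_cohort_params(n = 5000, seed = 29, p_extra_training = 1)
  cohort <- generate_cohort(p)
  m <- improved_health_model(cohort, adjust = c("age", "bmi", "distance_km"))
  expect_gte(2.49, m$crude$ci[1])
  expect_lte(2.49, m$crude$ci[2])
  # crude OR equals the cross-product on the induced table by definition
  tab <- m$table
  expect_equal(m$crude$or, (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1]),
               tolerance = 1e-12)
  # adjustment for background covariates leaves the estimate robust
  adj <- m$adjusted$coefficients
  row <- adj[adj$term == "high_additional_pa", ]
  expect_gte(2.49, row$or_low)
  expect_lte(2.49, row$or_high)
})

test_that("degenerate splits are rejected", {
  cohort <- homogeneous_cohort(10, prep_weeks = 2, weekly_prep = 60)
  # every record totals 120 additional minutes, all below 450
  expect_error(improved_health_model(cohort), "empty stratum")
  lone <- fixture_cohort()[4:6, ]
  expect_error(improved_health_model(lone), "no extra-training records")
})

test_that("group comparisons cover the background variables", {
  cohort <- generate_cohort(marikenloop_preset())
  cmp <- compare_extra_training(cohort)
  expect_setequal(
    cmp$variable,
    c("age", "bmi", "weekly_min_prep", "bmi_category", "health_status",
      "training_mode", "distance_km")
  )
  expect_true(all(cmp$p_value >= 0 & cmp$p_value <= 1))
  expect_equal(cmp$test[cmp$variable == "age"], "welch_t")
  expect_equal(cmp$test[cmp$variable == "distance_km"], "chi_square")
})

test_that("finite-population sample size reproduces the survey planning value", {
  expect_equal(sample_size_finite_population(7304), 365L)
  # no finite-population correction in the limit: z^2/(4 e^2) = 384.16
  expect_equal(sample_size_finite_population(1e9), 384L)
})

test_that("required sample size shrinks with the margin and the correction", {
  margins <- c(0.02, 0.03, 0.05, 0.1)
  ns <- sapply(margins, function(e) {
    sample_size_finite_population(7304, margin = e)
  })
  expect_true(all(diff(ns) < 0))
  # FPC always reduces the infinite-population requirement, monotonically
  pops <- c(500, 2000, 7304, 5e4, 1e7)
  ns2 <- sapply(pops, sample_size_finite_population)
  expect_true(all(diff(ns2) >= 0))
  expect_true(all(ns2 <= 385))
})
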