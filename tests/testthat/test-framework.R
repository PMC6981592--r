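test_that("inactive-count step rounds only for presentation", {
  n <- compute_inactive_count(7304, 0.32, 0.68)
  expect_equal(as.numeric(n), 1589)
  expect_equal(attr(n, "raw"), 7304 * 0.32 * 0.68, tolerance = 1e-12)
  expect_equal(as.numeric(compute_inactive_count(0, 0.5, 0.5)), 0)
  expect_equal(as.numeric(compute_inactive_count(100, 1, 1)), 100)
  expect_error(compute_inactive_count(-1, 0.5, 0.5))
})

test_that("per-participant additional minutes follow weeks x (prep - cf)", {
  expect_equal(additional_minutes_per_participant(8.8, 64, 127), 554.4)
  expect_equal(additional_minutes_per_participant(10, 60, 60), 0)
  expect_equal(additional_minutes_per_participant(1, 0, 75), 75)
  expect_error(additional_minutes_per_participant(0, 10, 20), "positive")
})

test_that("total minutes, QALYs and money carry raw and presented values", {
  g <- total_additional_minutes(1589, 565)
  expect_equal(as.numeric(g), 897785)
  expect_equal(attr(g, "presented"), 898000)
  expect_equal(as.numeric(total_additional_minutes(0, 565)), 0)
  expect_equal(as.numeric(total_additional_minutes(1, 75)), 75)

  h <- minutes_to_qalys(898000, 0.0000074)
  expect_equal(as.numeric(h), 6.6452, tolerance = 1e-12)
  expect_equal(attr(h, "presented"), 6.6)
  expect_equal(as.numeric(minutes_to_qalys(0)), 0)
  expect_equal(as.numeric(minutes_to_qalys(1 / 0.0000074, 0.0000074)), 1)

  i <- monetize(6.6452, c(20000, 80000))
  expect_equal(unname(as.numeric(i)), c(132904, 531616), tolerance = 1e-9)
  expect_equal(unname(attr(i, "presented")), c(133000, 532000))
  expect_equal(unname(as.numeric(monetize(0, c(20000)))), 0)
})

test_that("the QALY-per-minute coefficient derives from the weekly block", {
  q <- qaly_per_minute_from_block(0.0106768, 30, 48)
  expect_equal(as.numeric(q), 0.0000074)
  expect_equal(attr(q, "raw"), 0.0106768 / 1440, tolerance = 1e-15)
  # doubling the weekly block halves the coefficient
  expect_equal(attr(qaly_per_minute_from_block(0.0106768, 60, 48), "raw"),
               attr(q, "raw") / 2, tolerance = 1e-15)
})

test_that("the aggregate preset reproduces the published impact chain", {
  res <- run_framework(marikenloop_framework_inputs())
  expect_equal(res$presented$n_inactive, 1589)
  expect_equal(res$additional_min_per_week, 63)
  expect_equal(res$additional_min_per_participant, 565)
  # mean-of-products overrides, product-of-means stays visible
  expect_equal(res$additional_min_per_participant_formula, 554.4)
  expect_equal(res$presented$total_additional_minutes, 898000)
  expect_equal(res$presented$qalys, 6.6)
  expect_equal(unname(res$presented$monetary_value), c(133000, 532000))
  # rounding never feeds back: raw chain is exact
  expect_equal(res$total_additional_minutes, 7304 * 0.32 * 0.68 * 565,
               tolerance = 1e-12)
  expect_equal(res$qalys, res$total_additional_minutes * 0.0000074,
               tolerance = 1e-12)
  expect_equal(unname(res$monetary_value), res$qalys * c(20000, 80000),
               tolerance = 1e-12)
})

test_that("zero preparers, zero impact", {
  inputs <- framework_inputs(7304, 0, 0.68, prep_weeks = 8.8,
                             cf_min_per_week = 64, prep_min_per_week = 127)
  res <- run_framework(inputs)
  expect_equal(res$total_additional_minutes, 0)
  expect_equal(res$qalys, 0)
  expect_true(all(res$monetary_value == 0))
})

test_that("the chain is linear in the participant count", {
  base <- run_framework(marikenloop_framework_inputs())
  big <- marikenloop_framework_inputs()
  big$participants <- big$participants * 10
  scaled <- run_framework(big)
  expect_equal(scaled$total_additional_minutes,
               10 * base$total_additional_minutes, tolerance = 1e-12)
  expect_equal(scaled$qalys, 10 * base$qalys, tolerance = 1e-12)
  expect_equal(scaled$monetary_value, 10 * base$monetary_value,
               tolerance = 1e-12)
  # threshold ratio is exact on raw values
  expect_equal(unname(base$monetary_value["80000"] /
                        base$monetary_value["20000"]), 4)
})

test_that("negative additional minutes are floored with a warning", {
  inputs <- framework_inputs(1000, 0.5, 0.5, prep_weeks = 5,
                             cf_min_per_week = 100, prep_min_per_week = 80)
  expect_warning(res <- run_framework(inputs), "floored")
  expect_equal(res$total_additional_minutes, 0)
  expect_equal(res$n_floored, 1L)
})

test_that("per-record and aggregate modes agree exactly on homogeneous cohorts", {
  cohort <- homogeneous_cohort(40, prep_weeks = 10, weekly_prep = 120,
                               weekly_cf = 0)
  from_records <- run_framework_from_records(cohort)
  aggregate <- run_framework(framework_inputs(
    participants = 40, p_extra = 1, p_inactive = 1,
    prep_weeks = 10, cf_min_per_week = 0, prep_min_per_week = 120
  ))
  expect_equal(from_records$total_additional_minutes, 40 * 1200)
  expect_equal(from_records$total_additional_minutes,
               aggregate$total_additional_minutes, tolerance = 1e-9)
  expect_equal(from_records$qalys, aggregate$qalys, tolerance = 1e-9)
  expect_equal(from_records$monetary_value, aggregate$monetary_value,
               tolerance = 1e-9)
})

test_that("record mode derives B and C from the cohort and scales to A", {
  cohort <- fixture_cohort()
  res <- suppressWarnings(run_framework_from_records(cohort))
  expect_equal(res$inputs$p_extra, 0.5)
  expect_equal(res$inputs$p_inactive, 2 / 3)  # records 1, 2 of 3 trainers
  # records 1 and 2: 600 + 8 * 120 = 1560 additional minutes
  expect_equal(res$total_additional_minutes, 1560)
  scaled <- run_framework_from_records(cohort, participants = 60)
  expect_equal(scaled$total_additional_minutes, 10 * 1560, tolerance = 1e-9)
})

test_that("record mode rejects cohorts it cannot estimate from", {
  expect_error(run_framework_from_records(fixture_cohort()[0, ]), "empty")
  expect_error(run_framework_from_records(fixture_cohort()[4:6, ]),
               "no extra-training")
})

test_that("per-record mode converges to the generator-implied chain", {
  # Independent oracle: estimate E[B], E[C] and the mean floored total
  # among inactive extra trainers directly from the component
  # distributions, then chain by hand. The per-record pipeline at large n
  # must land on the same value (within Monte-Carlo error) - note this
  # sits above the all-trainer mean-of-totals because conditioning on a
  # low counterfactual raises the preparation-minus-counterfactual gap.
  set.seed(77)
  n_mc <- 200000
  draw <- function(n, mean, sd, lo, hi) {
    x <- numeric(0)
    while (length(x) < n) {
      y <- rnorm(n, mean, sd)
      x <- c(x, y[y >= lo & y <= hi])
    }
    x[seq_len(n)]
  }
  prep_w <- round(draw(n_mc, 2.4, 1.0, 0, 7)) * draw(n_mc, 52.1, 23.3, 0, 220)
  cf_w <- round(draw(n_mc, 1.5, 1.0, 0, 4)) * draw(n_mc, 41.6, 19.0, 0, 120)
  weeks <- round(draw(n_mc, 8.8, 5.4, 1, 30))
  inactive <- cf_w < 75
  mean_total_oracle <- mean(pmax(weeks[inactive] *
                                   (prep_w[inactive] - cf_w[inactive]), 0))
  h_oracle <- 7304 * 0.32 * mean(inactive) * mean_total_oracle * 0.0000074

  cohort <- generate_cohort(synthetic_cohort_params(n = 50000, seed = 21))
  res <- suppressWarnings(
    run_framework_from_records(cohort, participants = 7304)
  )
  expect_equal(res$qalys, h_oracle, tolerance = 0.05)
})

test_that("threshold sweeps are monotone and match monetize", {
  inputs <- marikenloop_framework_inputs()
  sweep <- threshold_sweep(inputs, c(80000, 20000, 50000))
  expect_equal(sweep$threshold, c(20000, 50000, 80000))
  expect_true(all(diff(sweep$value_raw) > 0))
  expect_equal(sweep$value_presented[c(1, 3)], c(133000, 532000))
  single <- threshold_sweep(inputs, 20000)
  h <- run_framework(inputs)$qalys
  expect_equal(single$value_raw, unname(as.numeric(monetize(h, 20000))))
})

test_that("JSON reports round-trip the raw and presented chain", {
  res <- run_framework(marikenloop_framework_inputs())
  path <- withr::local_tempfile(fileext = ".json")
  framework_report_json(res, path)
  back <- jsonlite::fromJSON(path)
  expect_equal(back$schema_version, "1.0")
  expect_equal(back$raw$total_additional_minutes,
               res$total_additional_minutes)
  expect_equal(back$raw$qalys, res$qalys, tolerance = 1e-12)
  expect_equal(back$presented$qalys, 6.6)
  expect_equal(back$presented$monetary_value$`80000`, 532000)
})

test_that("framework inputs load from YAML with validation", {
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(participants = 7304, p_extra = 0.32,
                        p_inactive = 0.68, mean_additional_total = 565),
                   path)
  inputs <- framework_inputs_from_yaml(path)
  expect_equal(run_framework(inputs)$presented$qalys, 6.6)
  yaml::write_yaml(list(participants = 10, bogus = 1), path)
  expect_error(framework_inputs_from_yaml(path), "unknown framework input")
})
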