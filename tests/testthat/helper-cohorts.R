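# Shared fixtures: small hand-built cohorts and independent oracles.

# A valid six-record cohort: three extra trainers (one initially active),
# three non-trainers.
fixture_cohort <- function() {
  rbind(
    participant_record(42, 67.5, 1.70, 5, "individual", 4, 2, 60, TRUE,
                       prep_weeks = 10, pa_sessions_per_week_cf = 1,
                       pa_min_per_session_cf = 60, health_change = 1),
    participant_record(35, 60.0, 1.65, 7.5, "group", 3, 3, 40, TRUE,
                       prep_weeks = 8, pa_sessions_per_week_cf = 0,
                       pa_min_per_session_cf = 0, health_change = 2),
    participant_record(51, 80.0, 1.72, 10, "individual", 3, 2, 50, TRUE,
                       prep_weeks = 6, pa_sessions_per_week_cf = 2,
                       pa_min_per_session_cf = 45, health_change = 0),
    participant_record(28, 55.0, 1.60, 5, "group", 5, 1, 30, FALSE),
    participant_record(44, 70.0, 1.75, 10, "individual", 4, 0, 0, FALSE),
    participant_record(60, 72.0, 1.68, 5, "group", 2, 2, 35, FALSE)
  )
}

# A perfectly homogeneous cohort of extra trainers (for the
# mean-of-products = product-of-means identity).
homogeneous_cohort <- function(n = 20, prep_weeks = 10,
                               weekly_prep = 120, weekly_cf = 0) {
  do.call(rbind, replicate(n, simplify = FALSE,
    participant_record(40, 65, 1.70, 5, "individual", 3,
                       1, weekly_prep, TRUE,
                       prep_weeks = prep_weeks,
                       pa_sessions_per_week_cf = if (weekly_cf > 0) 1 else 0,
                       pa_min_per_session_cf = weekly_cf,
                       health_change = 1)
  ))
}

# Independent truncated-normal moment oracle by numerical integration
# (the generator itself uses rejection sampling, never this formula).
trunc_moments_oracle <- function(mean, sd, lower, upper) {
  z <- stats::pnorm(upper, mean, sd) - stats::pnorm(lower, mean, sd)
  m1 <- stats::integrate(function(x) x * stats::dnorm(x, mean, sd),
                         lower, upper, rel.tol = 1e-10)$value / z
  m2 <- stats::integrate(function(x) x^2 * stats::dnorm(x, mean, sd),
                         lower, upper, rel.tol = 1e-10)$value / z
  c(mean = m1, sd = sqrt(m2 - m1^2))
}
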