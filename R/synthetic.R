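# Seeded synthetic survey cohorts. The generator reproduces the marginal
# structure of the Marikenloop 2017 respondent sample (truncated-normal
# continuous variables, categorical proportions) plus one injected
# dependency: the odds of reporting improved health are multiplied by
# `improvement_or` for participants whose total additional vigorous PA
# exceeds `pa_split_min` minutes. No other between-variable correlation is
# modelled.

# Truncation ranges: the observed min-max of each survey variable.
TRUNC_RANGES <- list(
  age = c(13, 74),
  weight = c(43, 120),
  height = c(1.50, 1.90),
  prep_weeks = c(1, 30),
  sessions_prep = c(0, 7),
  min_per_session_prep = c(0, 220),
  sessions_cf = c(0, 4),
  min_per_session_cf = c(0, 120)
)

#' Synthetic cohort parameters
#'
#' Builds the parameter set for [generate_cohort()]. Defaults reproduce
#' the marginal distributions of the Marikenloop 2017 respondent sample:
#' continuous variables are normals truncated to the observed ranges,
#' categorical variables use the observed proportions. The single injected
#' dependency is a two-level logistic model for health improvement: the
#' baseline probability applies to participants with at most
#' `pa_split_min` total additional minutes, and the odds are multiplied by
#' `improvement_or` above that split.
#'
#' @param n Cohort size.
#' @param seed Integer random seed; the same parameters and seed always
#'   produce the identical cohort.
#' @param age_mean,age_sd Age distribution in years.
#' @param weight_mean,weight_sd Body weight in kg.
#' @param height_mean,height_sd Body height in m.
#' @param p_distance Probabilities of running 5, 7.5 and 10 km.
#' @param p_individual_training Probability of training individually
#'   rather than in a group.
#' @param p_extra_training Probability of having performed additional
#'   training for the event.
#' @param prep_weeks_mean,prep_weeks_sd Preparation period in weeks
#'   (extra trainers).
#' @param sessions_prep_mean,sessions_prep_sd Vigorous-PA sessions per
#'   week during preparation.
#' @param min_per_session_prep_mean,min_per_session_prep_sd Minutes per
#'   session during preparation.
#' @param sessions_cf_mean,sessions_cf_sd Counterfactual sessions per week
#'   (extra trainers).
#' @param min_per_session_cf_mean,min_per_session_cf_sd Counterfactual
#'   minutes per session (extra trainers).
#' @param health_status_probs Probabilities of self-rated health 1-5.
#' @param improvement_baseline_p Probability of reporting improved health
#'   for extra trainers at or below the additional-PA split.
#' @param improvement_or Odds ratio of improvement above versus below the
#'   split (default 2.49).
#' @param pa_split_min Additional-PA split point in total minutes
#'   (default 450).
#' @return A list of class `synthetic_cohort_params`.
#' @seealso [marikenloop_preset()] for the published-sample preset.
#' @export
synthetic_cohort_params <- function(n,
                                    seed,
                                    age_mean = 42.3, age_sd = 11.9,
                                    weight_mean = 67.5, weight_sd = 10.1,
                                    height_mean = 1.70, height_sd = 0.06,
                                    p_distance = c(0.45, 0.22, 0.33),
                                    p_individual_training = 0.62,
                                    p_extra_training = 0.32,
                                    prep_weeks_mean = 8.8,
                                    prep_weeks_sd = 5.4,
                                    sessions_prep_mean = 2.4,
                                    sessions_prep_sd = 1.0,
                                    min_per_session_prep_mean = 52.1,
                                    min_per_session_prep_sd = 23.3,
                                    sessions_cf_mean = 1.5,
                                    sessions_cf_sd = 1.0,
                                    min_per_session_cf_mean = 41.6,
                                    min_per_session_cf_sd = 19.0,
                                    health_status_probs =
                                      c(0.002, 0.04, 0.55, 0.33, 0.08),
                                    improvement_baseline_p = 0.30,
                                    improvement_or = 2.49,
                                    pa_split_min = 450) {
  params <- list(
    n = n, seed = seed,
    age_mean = age_mean, age_sd = age_sd,
    weight_mean = weight_mean, weight_sd = weight_sd,
    height_mean = height_mean, height_sd = height_sd,
    p_distance = p_distance,
    p_individual_training = p_individual_training,
    p_extra_training = p_extra_training,
    prep_weeks_mean = prep_weeks_mean, prep_weeks_sd = prep_weeks_sd,
    sessions_prep_mean = sessions_prep_mean,
    sessions_prep_sd = sessions_prep_sd,
    min_per_session_prep_mean = min_per_session_prep_mean,
    min_per_session_prep_sd = min_per_session_prep_sd,
    sessions_cf_mean = sessions_cf_mean, sessions_cf_sd = sessions_cf_sd,
    min_per_session_cf_mean = min_per_session_cf_mean,
    min_per_session_cf_sd = min_per_session_cf_sd,
    health_status_probs = health_status_probs / sum(health_status_probs),
    improvement_baseline_p = improvement_baseline_p,
    improvement_or = improvement_or,
    pa_split_min = pa_split_min
  )
  validate_synthetic_params(params)
  structure(params, class = "synthetic_cohort_params")
}

validate_synthetic_params <- function(p) {
  stopifnot(
    length(p$n) == 1L, p$n >= 1, p$n == round(p$n),
    length(p$seed) == 1L, is.finite(p$seed),
    length(p$p_distance) == 3L,
    length(p$health_status_probs) == 5L,
    p$improvement_or > 0, p$pa_split_min >= 0
  )
  probs <- c(p$p_distance, p$p_individual_training, p$p_extra_training,
             p$health_status_probs, p$improvement_baseline_p)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(p$p_distance) - 1) > 1e-9 ||
      abs(sum(p$health_status_probs) - 1) > 1e-9) {
    stop("probability vectors must sum to 1", call. = FALSE)
  }
  sds <- c(p$age_sd, p$weight_sd, p$height_sd, p$prep_weeks_sd,
           p$sessions_prep_sd, p$min_per_session_prep_sd, p$sessions_cf_sd,
           p$min_per_session_cf_sd)
  if (any(sds < 0)) stop("standard deviations must be >= 0", call. = FALSE)
  invisible(p)
}

#' Marikenloop 2017 synthetic-cohort preset
#'
#' Parameters matching the descriptive statistics of the Marikenloop 2017
#' survey sample: n = 468 respondents, 32% extra trainers, mean age
#' 42.3 years, mean preparation 8.8 weeks, and the observed distance split
#' 45/22/33% over 5/7.5/10 km. The fixed seed (20170521, the event date)
#' makes the preset cohort reproducible.
#'
#' @return A `synthetic_cohort_params` object.
#' @examples
#' p <- marikenloop_preset()
#' p$n
#' @export
marikenloop_preset <- function() {
  synthetic_cohort_params(n = 468, seed = 20170521L)
}

# Rejection sampler for a normal truncated to [lower, upper]; redrawing
# rather than clipping avoids probability atoms at the boundaries.
rtrunc_norm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) {
    if (mean < lower || mean > upper) {
      stop("degenerate truncated normal: mean outside range", call. = FALSE)
    }
    return(rep(mean, n))
  }
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo) > 0L) {
    draw <- stats::rnorm(length(todo), mean, sd)
    ok <- draw >= lower & draw <= upper
    out[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
  }
  out
}

# Exact mean/sd of the truncated normal by numerical integration; used as
# the independent oracle when checking generator moments.
trunc_norm_moments <- function(mean, sd, lower, upper) {
  z <- stats::pnorm(upper, mean, sd) - stats::pnorm(lower, mean, sd)
  m1 <- stats::integrate(function(x) x * stats::dnorm(x, mean, sd),
                         lower, upper, rel.tol = 1e-10)$value / z
  m2 <- stats::integrate(function(x) x^2 * stats::dnorm(x, mean, sd),
                         lower, upper, rel.tol = 1e-10)$value / z
  c(mean = m1, sd = sqrt(m2 - m1^2))
}

#' Generate a synthetic survey cohort
#'
#' Draws `params$n` participant records. Continuous variables come from
#' normals truncated (by rejection) to the observed survey ranges;
#' session counts and preparation weeks are rounded to integers after
#' sampling; categorical variables use the stated probabilities.
#' Preparation-conditional fields are drawn only for extra-training
#' records. Health change is drawn so that the probability of improvement
#' follows the two-level logistic model described in
#' [synthetic_cohort_params()]; improved records report +1 or +2
#' (somewhat/much better, 88/12%), non-improved records 0 or -1
#' (93/7%). The same parameters and seed always yield the identical
#' cohort.
#'
#' @param params A `synthetic_cohort_params` object.
#' @return A cohort data frame that passes [validate_cohort()] in strict
#'   mode.
#' @examples
#' cohort <- generate_cohort(marikenloop_preset())
#' mean(cohort$extra_training)
#' @export
generate_cohort <- function(params) {
  if (!inherits(params, "synthetic_cohort_params")) {
    stop("params must be created by synthetic_cohort_params()",
         call. = FALSE)
  }
  validate_synthetic_params(params)
  n <- as.integer(params$n)
  set.seed(as.integer(params$seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion")
  r <- TRUNC_RANGES

  records <- data.frame(
    age = round(rtrunc_norm(n, params$age_mean, params$age_sd,
                            r$age[1], r$age[2])),
    weight_kg = rtrunc_norm(n, params$weight_mean, params$weight_sd,
                            r$weight[1], r$weight[2]),
    height_m = rtrunc_norm(n, params$height_mean, params$height_sd,
                           r$height[1], r$height[2]),
    distance_km = sample(VALID_DISTANCES, n, replace = TRUE,
                         prob = params$p_distance),
    training_mode = sample(c("individual", "group"), n, replace = TRUE,
                           prob = c(params$p_individual_training,
                                    1 - params$p_individual_training)),
    health_status = sample(1:5, n, replace = TRUE,
                           prob = params$health_status_probs),
    pa_sessions_per_week_prep =
      round(rtrunc_norm(n, params$sessions_prep_mean,
                        params$sessions_prep_sd,
                        r$sessions_prep[1], r$sessions_prep[2])),
    pa_min_per_session_prep =
      rtrunc_norm(n, params$min_per_session_prep_mean,
                  params$min_per_session_prep_sd,
                  r$min_per_session_prep[1], r$min_per_session_prep[2]),
    extra_training = stats::runif(n) < params$p_extra_training,
    prep_weeks = NA_real_,
    pa_sessions_per_week_cf = NA_real_,
    pa_min_per_session_cf = NA_real_,
    health_change = NA_real_,
    stringsAsFactors = FALSE
  )

  extra <- which(records$extra_training)
  n_extra <- length(extra)
  if (n_extra > 0L) {
    records$prep_weeks[extra] <-
      pmax(1, round(rtrunc_norm(n_extra, params$prep_weeks_mean,
                                params$prep_weeks_sd,
                                r$prep_weeks[1], r$prep_weeks[2])))
    records$pa_sessions_per_week_cf[extra] <-
      round(rtrunc_norm(n_extra, params$sessions_cf_mean,
                        params$sessions_cf_sd,
                        r$sessions_cf[1], r$sessions_cf[2]))
    records$pa_min_per_session_cf[extra] <-
      rtrunc_norm(n_extra, params$min_per_session_cf_mean,
                  params$min_per_session_cf_sd,
                  r$min_per_session_cf[1], r$min_per_session_cf[2])

    additional_total <- records$prep_weeks[extra] *
      (records$pa_sessions_per_week_prep[extra] *
         records$pa_min_per_session_prep[extra] -
         records$pa_sessions_per_week_cf[extra] *
         records$pa_min_per_session_cf[extra])
    high <- additional_total > params$pa_split_min
    log_odds <- stats::qlogis(params$improvement_baseline_p) +
      log(params$improvement_or) * high
    improved <- stats::runif(n_extra) < stats::plogis(log_odds)

    change <- numeric(n_extra)
    n_imp <- sum(improved)
    if (n_imp > 0L) {
      change[improved] <- sample(c(1, 2), n_imp, replace = TRUE,
                                 prob = c(0.88, 0.12))
    }
    if (n_extra - n_imp > 0L) {
      change[!improved] <- sample(c(0, -1), n_extra - n_imp,
                                  replace = TRUE, prob = c(0.93, 0.07))
    }
    records$health_change[extra] <- change
  }
  records
}

#' Write synthetic-cohort parameters to YAML
#'
#' @param params A `synthetic_cohort_params` object.
#' @param path Output YAML file path.
#' @return `path`, invisibly.
#' @export
write_params_yaml <- function(params, path) {
  stopifnot(inherits(params, "synthetic_cohort_params"))
  yaml::write_yaml(unclass(params), path, precision = 15)
  invisible(path)
}

#' Read synthetic-cohort parameters from YAML
#'
#' @param path YAML file previously written by [write_params_yaml()] (or
#'   hand-authored with the same keys; missing keys fall back to the
#'   defaults of [synthetic_cohort_params()]).
#' @return A `synthetic_cohort_params` object.
#' @export
read_params_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(synthetic_cohort_params))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    stop("unknown parameter(s) in YAML: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(synthetic_cohort_params, raw)
}
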