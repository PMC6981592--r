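# Descriptive and inferential layer for survey cohorts: descriptive
# tables, extra-training group comparisons, 2x2 odds ratios, binary
# logistic regression and the finite-population sample-size check.

NUMERIC_SUMMARY_VARS <- c(
  "age", "weight_kg", "height_m", "bmi", "distance_km", "health_status",
  "pa_sessions_per_week_prep", "pa_min_per_session_prep",
  "weekly_min_prep", "prep_weeks", "pa_sessions_per_week_cf",
  "pa_min_per_session_cf", "weekly_min_cf", "additional_min_per_week",
  "additional_min_total", "health_change"
)

CATEGORICAL_SUMMARY_VARS <- c(
  "distance_km", "training_mode", "health_status", "bmi_category",
  "extra_training", "initially_inactive", "health_improved"
)

#' Descriptive cohort summary
#'
#' Computes, for every schema and derived variable, the number of
#' non-missing values, minimum, maximum, mean and sample standard
#' deviation, plus level counts and proportions for the categorical
#' variables. Preparation-conditional variables are summarized over the
#' extra-training subset only (their values are missing elsewhere by
#' construction).
#'
#' @param records A validated cohort data frame.
#' @param who_threshold WHO vigorous threshold passed to [derive()].
#' @return An object of class `cohort_summary`: a list with elements
#'   `numeric` (variable, n, min, max, mean, sd), `categorical`
#'   (variable, level, count, proportion) and `n_records`.
#' @export
summarize_cohort <- function(records, who_threshold = 75) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) stop("empty cohort", call. = FALSE)
  full <- add_derived(records, who_threshold)

  num <- do.call(rbind, lapply(NUMERIC_SUMMARY_VARS, function(v) {
    x <- as.numeric(full[[v]])
    x <- x[!is.na(x)]
    if (length(x) == 0L) {
      return(data.frame(variable = v, n = 0L, min = NA_real_,
                        max = NA_real_, mean = NA_real_, sd = NA_real_))
    }
    data.frame(variable = v, n = length(x), min = min(x), max = max(x),
               mean = mean(x), sd = stats::sd(x))
  }))

  cat_ <- do.call(rbind, lapply(CATEGORICAL_SUMMARY_VARS, function(v) {
    x <- full[[v]]
    x <- x[!is.na(x)]
    if (length(x) == 0L) return(NULL)
    tab <- table(x)
    data.frame(variable = v, level = names(tab),
               count = as.integer(tab),
               proportion = as.numeric(tab) / length(x),
               stringsAsFactors = FALSE)
  }))
  rownames(num) <- rownames(cat_) <- NULL

  structure(list(numeric = num, categorical = cat_,
                 n_records = nrow(records)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, digits = 3, ...) {
  cat("Cohort summary (", x$n_records, " records)\n\n", sep = "")
  num <- x$numeric
  num[c("min", "max", "mean", "sd")] <-
    lapply(num[c("min", "max", "mean", "sd")], round, digits)
  print(num, row.names = FALSE)
  cat("\nCategorical variables\n")
  cat_ <- x$categorical
  cat_$proportion <- round(cat_$proportion, digits)
  print(cat_, row.names = FALSE)
  invisible(x)
}

#' Export a cohort summary as CSV
#'
#' Writes the numeric block to `<path>` and the categorical block to a
#' sibling file with suffix `_categorical.csv`.
#'
#' @param x A `cohort_summary`.
#' @param path Output CSV path for the numeric block.
#' @return Character vector of the two paths written, invisibly.
#' @export
write_cohort_summary <- function(x, path) {
  stopifnot(inherits(x, "cohort_summary"))
  utils::write.csv(x$numeric, path, row.names = FALSE)
  cat_path <- sub("\\.csv$", "_categorical.csv", path)
  if (identical(cat_path, path)) cat_path <- paste0(path, "_categorical.csv")
  utils::write.csv(x$categorical, cat_path, row.names = FALSE)
  invisible(c(path, cat_path))
}

#' Welch two-sample t-test
#'
#' Unequal-variance (Welch) t-test with Welch-Satterthwaite degrees of
#' freedom and a two-sided p-value, the appropriate default when group
#' variances may differ.
#'
#' @param x,y Numeric samples, each with at least two non-missing values.
#' @return List with `statistic`, `df`, `p_value`, `mean_x`, `mean_y`.
#' @export
welch_t_test <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) {
    stop("each sample needs at least 2 non-missing values", call. = FALSE)
  }
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    stop("both samples have zero variance", call. = FALSE)
  }
  fit <- stats::t.test(x, y, var.equal = FALSE)
  list(statistic = unname(fit$statistic), df = unname(fit$parameter),
       p_value = fit$p.value, mean_x = mean(x), mean_y = mean(y))
}

#' Pearson chi-square test of independence
#'
#' Pearson chi-square on an r x c contingency table, without continuity
#' correction, with (r-1)(c-1) degrees of freedom.
#'
#' @param table Matrix of non-negative counts, at least 2x2.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
chi_square_test <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2L || ncol(table) < 2L) {
    stop("table must be at least 2x2", call. = FALSE)
  }
  if (any(table < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("degenerate table: zero row or column margin", call. = FALSE)
  }
  fit <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(fit$statistic), df = unname(fit$parameter),
       p_value = fit$p.value)
}

#' 2x2 odds ratio with Wald confidence interval
#'
#' For the table `[a b; c d]` (rows: exposed/unexposed, columns:
#' event/no event) computes the cross-product odds ratio `(a*d)/(b*c)`,
#' the standard error of the log odds ratio
#' `sqrt(1/a + 1/b + 1/c + 1/d)`, a Wald confidence interval and a Wald
#' two-sided p-value. If any cell is zero, the Haldane-Anscombe
#' correction (0.5 added to every cell) is applied first.
#'
#' @param a,b,c,d Non-negative cell counts.
#' @param conf_level Confidence level for the Wald interval (default
#'   0.95).
#' @return Object of class `odds_ratio_result`: list with `counts`, `or`,
#'   `log_or`, `se_log_or`, `ci` (length-2 vector), `p_value`,
#'   `haldane_corrected`.
#' @examples
#' odds_ratio_2x2(30, 70, 15, 85)
#' @export
odds_ratio_2x2 <- function(a, b, c, d, conf_level = 0.95) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  tab <- matrix(counts, 2, 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("odds ratio undefined: zero row or column margin", call. = FALSE)
  }
  corrected <- any(counts == 0)
  w <- if (corrected) counts + 0.5 else counts
  log_or <- log(w["a"]) + log(w["d"]) - log(w["b"]) - log(w["c"])
  se <- sqrt(sum(1 / w))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(
    counts = counts,
    or = unname(exp(log_or)),
    log_or = unname(log_or),
    se_log_or = unname(se),
    ci = unname(exp(log_or + c(-1, 1) * z * se)),
    p_value = unname(2 * stats::pnorm(-abs(log_or / se))),
    conf_level = conf_level,
    haldane_corrected = corrected
  ), class = "odds_ratio_result")
}

#' @export
print.odds_ratio_result <- function(x, digits = 3, ...) {
  cat(sprintf("Odds ratio: %.*f (%.0f%% CI %.*f-%.*f), p = %.4g\n",
              digits, x$or, 100 * x$conf_level, digits, x$ci[1],
              digits, x$ci[2], x$p_value))
  if (x$haldane_corrected) {
    cat("(Haldane-Anscombe 0.5 correction applied: zero cell present)\n")
  }
  invisible(x)
}

#' Binary logistic regression
#'
#' Maximum-likelihood logistic regression of a binary outcome on a
#' covariate matrix, fitted by iteratively reweighted least squares
#' (tight convergence tolerance, at most 100 iterations). Coefficients
#' are reported with Wald standard errors, p-values, and
#' exponentiated as odds ratios with Wald confidence intervals.
#' Complete or quasi-complete separation (diverging coefficients or
#' non-convergence) is reported as an error.
#'
#' @param y Binary outcome vector (logical or 0/1).
#' @param X Covariate matrix or data frame (an intercept is added).
#' @param conf_level Confidence level for the odds-ratio intervals.
#' @return Object of class `logistic_fit`: list with `coefficients` (a
#'   data frame with term, estimate, se, z, p_value, or, or_low,
#'   or_high), `converged`, `n`, and the underlying `glm` object as
#'   `model`.
#' @export
logistic_fit <- function(y, X, conf_level = 0.95) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("y must be binary (0/1)", call. = FALSE)
  X <- as.data.frame(X)
  if (nrow(X) != length(y)) stop("y and X sizes differ", call. = FALSE)
  dat <- cbind(data.frame(.y = y), X)
  fit <- stats::glm(.y ~ ., family = stats::binomial(), data = dat,
                    control = stats::glm.control(epsilon = 1e-10,
                                                 maxit = 100))
  if (!fit$converged) {
    stop("logistic regression did not converge (possible separation)",
         call. = FALSE)
  }
  coefs <- summary(fit)$coefficients
  if (any(abs(coefs[, "Estimate"]) > 15)) {
    stop("separation detected: divergent coefficient estimates",
         call. = FALSE)
  }
  if (fit$rank < ncol(stats::model.matrix(fit))) {
    stop("rank-deficient covariate matrix", call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(
    coefficients = data.frame(
      term = rownames(coefs),
      estimate = coefs[, "Estimate"],
      se = coefs[, "Std. Error"],
      z = coefs[, "z value"],
      p_value = coefs[, "Pr(>|z|)"],
      or = exp(coefs[, "Estimate"]),
      or_low = exp(coefs[, "Estimate"] - z * coefs[, "Std. Error"]),
      or_high = exp(coefs[, "Estimate"] + z * coefs[, "Std. Error"]),
      row.names = NULL, stringsAsFactors = FALSE
    ),
    converged = fit$converged,
    n = length(y),
    conf_level = conf_level,
    model = fit
  ), class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, digits = 3, ...) {
  cat("Binary logistic regression (n = ", x$n, ")\n", sep = "")
  tab <- x$coefficients
  num <- setdiff(names(tab), "term")
  tab[num] <- lapply(tab[num], signif, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Improved-health model across an additional-PA split
#'
#' Among extra-training participants with a reported health change,
#' dichotomizes the total additional vigorous-PA minutes at
#' `pa_split_min` (strictly greater counts as the high group) and
#' estimates the odds ratio of reporting improved health for the high
#' versus the low group: crude from the induced 2x2 table, and — when
#' `adjust` names covariates such as `"age"`, `"bmi"`,
#' `"distance_km"` — adjusted by logistic regression.
#'
#' @param records A validated cohort data frame.
#' @param pa_split_min Split point in total additional minutes
#'   (default 450).
#' @param adjust Character vector of covariate names to adjust for
#'   (schema or derived variables); empty for the crude model only.
#' @param who_threshold WHO vigorous threshold passed to [derive()].
#' @return Object of class `improved_health_model`: list with `crude` (an
#'   `odds_ratio_result`), `adjusted` (a `logistic_fit` or `NULL`),
#'   `table` (the 2x2 counts), `n`, `pa_split_min`.
#' @export
improved_health_model <- function(records, pa_split_min = 450,
                                  adjust = character(),
                                  who_threshold = 75) {
  full <- add_derived(records, who_threshold)
  full <- full[full$extra_training %in% TRUE &
                 !is.na(full$health_change), , drop = FALSE]
  if (nrow(full) == 0L) {
    stop("no extra-training records with a reported health change",
         call. = FALSE)
  }
  high <- full$additional_min_total > pa_split_min
  if (all(high) || all(!high)) {
    stop("empty stratum: all records on one side of the ", pa_split_min,
         "-minute split", call. = FALSE)
  }
  improved <- full$health_improved
  a <- sum(high & improved); b <- sum(high & !improved)
  c_ <- sum(!high & improved); d <- sum(!high & !improved)
  crude <- odds_ratio_2x2(a, b, c_, d)

  adjusted <- NULL
  if (length(adjust) > 0L) {
    missing_vars <- setdiff(adjust, names(full))
    if (length(missing_vars) > 0L) {
      stop("unknown adjustment covariate(s): ",
           paste(missing_vars, collapse = ", "), call. = FALSE)
    }
    X <- cbind(data.frame(high_additional_pa = as.numeric(high)),
               full[, adjust, drop = FALSE])
    adjusted <- logistic_fit(improved, X)
  }

  structure(list(
    crude = crude, adjusted = adjusted,
    table = matrix(c(a, b, c_, d), 2, 2, byrow = TRUE,
                   dimnames = list(c("high", "low"),
                                   c("improved", "not_improved"))),
    n = nrow(full), pa_split_min = pa_split_min
  ), class = "improved_health_model")
}

#' @export
print.improved_health_model <- function(x, ...) {
  cat("Improved-health model, additional-PA split at", x$pa_split_min,
      "min (n =", x$n, ")\n")
  print(x$table)
  cat("\nCrude ")
  print(x$crude)
  if (!is.null(x$adjusted)) {
    cat("\nAdjusted model:\n")
    print(x$adjusted)
  }
  invisible(x)
}

#' Group comparisons between extra trainers and the rest
#'
#' Compares extra-training versus non-extra-training participants on the
#' background variables: Welch t-tests for age, BMI and weekly
#' preparation minutes; chi-square tests for BMI category, self-rated
#' health, training mode and event distance.
#'
#' @param records A validated cohort data frame.
#' @param who_threshold WHO vigorous threshold passed to [derive()].
#' @return A data frame with columns `variable`, `test`, `statistic`,
#'   `df`, `p_value`.
#' @export
compare_extra_training <- function(records, who_threshold = 75) {
  full <- add_derived(records, who_threshold)
  g <- full$extra_training %in% TRUE
  if (all(g) || all(!g)) {
    stop("both extra-training groups must be non-empty", call. = FALSE)
  }
  rows <- list()
  for (v in c("age", "bmi", "weekly_min_prep")) {
    t <- welch_t_test(full[[v]][g], full[[v]][!g])
    rows[[v]] <- data.frame(variable = v, test = "welch_t",
                            statistic = t$statistic, df = t$df,
                            p_value = t$p_value)
  }
  for (v in c("bmi_category", "health_status", "training_mode",
              "distance_km")) {
    tab <- table(full[[v]], g)
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    if (nrow(tab) < 2L) next
    cs <- chi_square_test(tab)
    rows[[v]] <- data.frame(variable = v, test = "chi_square",
                            statistic = cs$statistic, df = cs$df,
                            p_value = cs$p_value)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Finite-population sample size for a proportion
#'
#' Required sample size to estimate a proportion within a margin of error
#' at a given confidence level, with the finite-population correction:
#' `n0 = z^2 p (1-p) / e^2`, then `n = n0 / (1 + n0 / N)`, rounded to the
#' nearest integer.
#'
#' @param population Finite population size N.
#' @param margin Margin of error e, in (0, 1) (default 0.05).
#' @param conf_level Confidence level (default 0.95).
#' @param p Assumed proportion (default 0.5, the conservative maximum).
#' @return Required sample size (integer).
#' @examples
#' sample_size_finite_population(7304)
#' @export
sample_size_finite_population <- function(population, margin = 0.05,
                                          conf_level = 0.95, p = 0.5) {
  stopifnot(population >= 1, margin > 0, margin < 1,
            conf_level > 0, conf_level < 1, p > 0, p < 1)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  n0 <- z^2 * p * (1 - p) / margin^2
  as.integer(round(n0 / (1 + n0 / population)))
}
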