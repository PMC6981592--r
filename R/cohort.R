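#' @keywords internal
"_PACKAGE"

# Column schema for participant survey cohorts. Order is fixed: it is the
# on-disk CSV contract. Conditional columns are only populated for records
# with extra_training = TRUE.
COHORT_COLUMNS <- c(
  "age", "weight_kg", "height_m", "distance_km", "training_mode",
  "health_status", "pa_sessions_per_week_prep", "pa_min_per_session_prep",
  "extra_training", "prep_weeks", "pa_sessions_per_week_cf",
  "pa_min_per_session_cf", "health_change"
)

CONDITIONAL_COLUMNS <- c(
  "prep_weeks", "pa_sessions_per_week_cf", "pa_min_per_session_cf",
  "health_change"
)

VALID_DISTANCES <- c(5, 7.5, 10)
VALID_TRAINING_MODES <- c("individual", "group")

#' Cohort CSV column schema
#'
#' Returns the fixed column order of the participant cohort CSV format.
#' All columns are numeric except `training_mode` (one of `"individual"`
#' or `"group"`); `extra_training` is written as 0/1. The four
#' preparation-conditional columns (`prep_weeks`,
#' `pa_sessions_per_week_cf`, `pa_min_per_session_cf`, `health_change`)
#' are empty for participants who did not train extra for the event.
#'
#' @return Character vector of column names in file order.
#' @export
cohort_schema <- function() COHORT_COLUMNS

#' Construct a single participant record
#'
#' Convenience constructor for a one-row cohort data frame, mainly useful
#' for examples and tests. Conditional fields default to `NA` and must be
#' supplied when `extra_training` is `TRUE`.
#'
#' @param age Age in whole years.
#' @param weight_kg Body weight in kilograms.
#' @param height_m Body height in meters.
#' @param distance_km Event distance: 5, 7.5 or 10 km.
#' @param training_mode `"individual"` or `"group"`.
#' @param health_status Self-rated health, ordinal 1 (poor) to 5 (excellent).
#' @param pa_sessions_per_week_prep Vigorous-activity sessions per week
#'   during the preparation period.
#' @param pa_min_per_session_prep Minutes per session during preparation.
#' @param extra_training Logical; did the participant train extra for the
#'   event?
#' @param prep_weeks Length of the preparation period in weeks (extra
#'   trainers only).
#' @param pa_sessions_per_week_cf Counterfactual sessions per week had the
#'   event not been organized (extra trainers only).
#' @param pa_min_per_session_cf Counterfactual minutes per session (extra
#'   trainers only).
#' @param health_change Self-rated health change over the preparation
#'   period, ordinal -2 (much worse) to +2 (much better); extra trainers
#'   only.
#' @return A one-row data frame following [cohort_schema()].
#' @examples
#' participant_record(42, 67.5, 1.70, 5, "individual", 4,
#'   2, 60, TRUE,
#'   prep_weeks = 10, pa_sessions_per_week_cf = 1,
#'   pa_min_per_session_cf = 30, health_change = 1
#' )
#' @export
participant_record <- function(age, weight_kg, height_m, distance_km,
                               training_mode, health_status,
                               pa_sessions_per_week_prep,
                               pa_min_per_session_prep,
                               extra_training,
                               prep_weeks = NA_real_,
                               pa_sessions_per_week_cf = NA_real_,
                               pa_min_per_session_cf = NA_real_,
                               health_change = NA_real_) {
  data.frame(
    age = age, weight_kg = weight_kg, height_m = height_m,
    distance_km = distance_km, training_mode = training_mode,
    health_status = health_status,
    pa_sessions_per_week_prep = pa_sessions_per_week_prep,
    pa_min_per_session_prep = pa_min_per_session_prep,
    extra_training = as.logical(extra_training),
    prep_weeks = prep_weeks,
    pa_sessions_per_week_cf = pa_sessions_per_week_cf,
    pa_min_per_session_cf = pa_min_per_session_cf,
    health_change = health_change,
    stringsAsFactors = FALSE
  )
}

# Per-row validation. Returns a data.frame of issues (row, field, message);
# zero rows when everything is valid.
cohort_issues <- function(records) {
  issues <- list()
  flag <- function(rows, field, message) {
    if (any(rows)) {
      issues[[length(issues) + 1L]] <<- data.frame(
        row = which(rows), field = field, message = message,
        stringsAsFactors = FALSE
      )
    }
  }
  bad_num <- function(x) !is.finite(x)

  flag(bad_num(records$age) | records$age < 0 |
         records$age != round(records$age), "age",
       "must be a non-negative whole number")
  flag(bad_num(records$weight_kg) | records$weight_kg <= 0, "weight_kg",
       "must be a positive number")
  flag(bad_num(records$height_m) | records$height_m <= 0, "height_m",
       "must be a positive number")
  flag(!records$distance_km %in% VALID_DISTANCES | is.na(records$distance_km),
       "distance_km", "must be one of 5, 7.5, 10")
  flag(!records$training_mode %in% VALID_TRAINING_MODES |
         is.na(records$training_mode),
       "training_mode", "must be 'individual' or 'group'")
  flag(!records$health_status %in% 1:5 | is.na(records$health_status),
       "health_status", "must be an integer 1-5")
  flag(bad_num(records$pa_sessions_per_week_prep) |
         records$pa_sessions_per_week_prep < 0 |
         records$pa_sessions_per_week_prep !=
           round(records$pa_sessions_per_week_prep),
       "pa_sessions_per_week_prep", "must be a non-negative whole number")
  flag(bad_num(records$pa_min_per_session_prep) |
         records$pa_min_per_session_prep < 0,
       "pa_min_per_session_prep", "must be a non-negative number")
  flag(is.na(records$extra_training), "extra_training",
       "must be 0/1 or TRUE/FALSE")

  extra <- records$extra_training %in% TRUE
  flag(extra & (bad_num(records$prep_weeks) | records$prep_weeks < 1 |
                  records$prep_weeks != round(records$prep_weeks)),
       "prep_weeks", "must be a positive whole number when extra_training=1")
  flag(extra & (bad_num(records$pa_sessions_per_week_cf) |
                  records$pa_sessions_per_week_cf < 0 |
                  records$pa_sessions_per_week_cf !=
                    round(records$pa_sessions_per_week_cf)),
       "pa_sessions_per_week_cf",
       "must be a non-negative whole number when extra_training=1")
  flag(extra & (bad_num(records$pa_min_per_session_cf) |
                  records$pa_min_per_session_cf < 0),
       "pa_min_per_session_cf",
       "must be a non-negative number when extra_training=1")
  flag(extra & (!records$health_change %in% (-2):2 |
                  is.na(records$health_change)),
       "health_change", "must be an integer -2..2 when extra_training=1")

  not_extra <- records$extra_training %in% FALSE
  for (col in CONDITIONAL_COLUMNS) {
    flag(not_extra & !is.na(records[[col]]), col,
         "must be empty when extra_training=0")
  }

  if (length(issues) == 0L) {
    return(data.frame(row = integer(), field = character(),
                      message = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, issues)
  out[order(out$row, out$field), , drop = FALSE]
}

#' Validate a participant cohort
#'
#' Checks every record against the schema invariants: positive
#' anthropometrics, valid distance/training-mode/ordinal codes, and the
#' conditional-field rule (preparation fields present if and only if
#' `extra_training` is true).
#'
#' @param records A cohort data frame following [cohort_schema()].
#' @param strict If `TRUE`, any invalid record raises an error naming the
#'   row and field. If `FALSE` (default), invalid records are dropped
#'   (listwise deletion) and counted.
#' @return The validated cohort, with attributes `n_dropped` (number of
#'   records removed) and `issues` (a data frame with columns `row`,
#'   `field`, `message` describing every violation found).
#' @export
validate_cohort <- function(records, strict = FALSE) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(COHORT_COLUMNS, names(records))
  if (length(missing_cols) > 0L) {
    stop("cohort is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  records <- records[, COHORT_COLUMNS]
  issues <- cohort_issues(records)
  if (strict && nrow(issues) > 0L) {
    first <- issues[1L, ]
    stop(sprintf(
      "invalid cohort record at row %d, field '%s': %s (%d issue(s) total)",
      first$row, first$field, first$message, nrow(issues)
    ), call. = FALSE)
  }
  bad_rows <- unique(issues$row)
  keep <- records[setdiff(seq_len(nrow(records)), bad_rows), , drop = FALSE]
  rownames(keep) <- NULL
  attr(keep, "n_dropped") <- length(bad_rows)
  attr(keep, "issues") <- issues
  keep
}

#' Read a participant cohort from CSV
#'
#' Reads a comma-separated, UTF-8 cohort file with a mandatory header in
#' the order given by [cohort_schema()]. Booleans are encoded 0/1 and the
#' conditional columns are empty for non-extra-trainers. Invalid records
#' are handled by listwise deletion (the survey analysis convention) unless
#' `strict = TRUE`.
#'
#' @param path Path to the CSV file.
#' @inheritParams validate_cohort
#' @return A validated cohort data frame; see [validate_cohort()] for the
#'   `n_dropped` and `issues` attributes.
#' @seealso [write_cohort()]
#' @export
read_cohort <- function(path, strict = FALSE) {
  if (!file.exists(path)) {
    stop("cohort file not found: ", path, call. = FALSE)
  }
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  header <- gsub('^"|"$', "", trimws(header))
  if (!identical(header, COHORT_COLUMNS)) {
    stop("malformed cohort header; expected columns: ",
         paste(COHORT_COLUMNS, collapse = ", "), call. = FALSE)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(training_mode = "character"),
                         na.strings = c("", "NA"))
  raw$extra_training <- as.logical(raw$extra_training)
  validate_cohort(raw, strict = strict)
}

#' Write a participant cohort to CSV
#'
#' Writes the cohort in the dialect [read_cohort()] expects: comma
#' separator, header row, decimal points, booleans as 0/1, conditional
#' fields empty for non-extra-trainers. `write_cohort()` followed by
#' [read_cohort()] is the identity on valid cohorts.
#'
#' @param records A cohort data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(records, path) {
  stopifnot(is.data.frame(records))
  out <- records[, COHORT_COLUMNS]
  out$extra_training <- as.integer(out$extra_training)
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Classify body mass index
#'
#' Standard WHO adult BMI categories with left-closed intervals:
#' underweight below 18.5, normal weight in \[18.5, 25), overweight in
#' \[25, 30), obesity at 30 and above.
#'
#' @param bmi Numeric vector of BMI values (kg/m^2), all positive.
#' @return Factor with levels `underweight`, `normal`, `overweight`,
#'   `obesity`.
#' @examples
#' classify_bmi(c(17, 23.4, 25, 30))
#' @export
classify_bmi <- function(bmi) {
  if (any(!is.na(bmi) & bmi <= 0)) {
    stop("bmi must be positive", call. = FALSE)
  }
  cut(bmi, breaks = c(0, 18.5, 25, 30, Inf), right = FALSE,
      labels = c("underweight", "normal", "overweight", "obesity"))
}

#' WHO vigorous-activity guideline check
#'
#' The WHO guideline for vigorous physical activity is at least 75 minutes
#' per week; exactly 75 minutes counts as meeting it.
#'
#' @param weekly_min Non-negative minutes of vigorous activity per week.
#' @param threshold Guideline threshold in minutes/week (default 75).
#' @return Logical vector: `TRUE` where the guideline is met.
#' @examples
#' classify_who_vigorous(c(0, 74.9, 75, 150))
#' @export
classify_who_vigorous <- function(weekly_min, threshold = 75) {
  if (any(!is.na(weekly_min) & weekly_min < 0)) {
    stop("weekly_min must be non-negative", call. = FALSE)
  }
  stopifnot(threshold > 0)
  weekly_min >= threshold
}

#' Compute per-record derived variables
#'
#' For each participant computes BMI and its category, weekly vigorous-PA
#' minutes during preparation (sessions x minutes/session) and under the
#' counterfactual of no event, the weekly and total additional minutes
#' (preparation minus counterfactual, totalled over the preparation weeks),
#' the initially-inactive indicator (counterfactual weekly minutes below
#' the WHO vigorous threshold) and the improved-health indicator (health
#' change of +1 or +2). Preparation-conditional derived variables are `NA`
#' for participants without extra training.
#'
#' @param records A validated cohort data frame.
#' @param who_threshold WHO vigorous-activity guideline in minutes/week
#'   (default 75).
#' @return A data frame with one row per record and columns `bmi`,
#'   `bmi_category`, `weekly_min_prep`, `weekly_min_cf`,
#'   `additional_min_per_week`, `additional_min_total`,
#'   `initially_inactive`, `health_improved`.
#' @examples
#' rec <- participant_record(42, 67.5, 1.70, 5, "individual", 4,
#'   2, 60, TRUE,
#'   prep_weeks = 10, pa_sessions_per_week_cf = 1,
#'   pa_min_per_session_cf = 60, health_change = 1
#' )
#' derive(rec)
#' @export
derive <- function(records, who_threshold = 75) {
  stopifnot(is.data.frame(records), who_threshold > 0)
  bmi <- records$weight_kg / records$height_m^2
  weekly_min_prep <- records$pa_sessions_per_week_prep *
    records$pa_min_per_session_prep
  weekly_min_cf <- records$pa_sessions_per_week_cf *
    records$pa_min_per_session_cf
  additional_min_per_week <- weekly_min_prep - weekly_min_cf
  data.frame(
    bmi = bmi,
    bmi_category = classify_bmi(bmi),
    weekly_min_prep = weekly_min_prep,
    weekly_min_cf = weekly_min_cf,
    additional_min_per_week = additional_min_per_week,
    additional_min_total = records$prep_weeks * additional_min_per_week,
    initially_inactive = !classify_who_vigorous(weekly_min_cf,
                                                who_threshold),
    health_improved = ifelse(is.na(records$health_change), NA,
                             records$health_change >= 1),
    stringsAsFactors = FALSE
  )
}

#' Append derived variables to a cohort
#'
#' Column-binds the output of [derive()] to the cohort; convenience for
#' downstream analyses that need both the raw and derived variables.
#'
#' @inheritParams derive
#' @return The cohort with the derived columns appended.
#' @export
add_derived <- function(records, who_threshold = 75) {
  cbind(records, derive(records, who_threshold))
}
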