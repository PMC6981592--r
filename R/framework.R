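# The health-impact chain for a mass participation sporting event:
#
#   participants (A) -> extra trainers (A x B) -> initially inactive
#   (A x B x C) -> total additional vigorous minutes
#   G = A x B x C x D x (F - E) -> QALYs H = G x q -> monetary value
#   I = H x V for each threshold V.
#
# All chained quantities are carried unrounded; presentation rounding
# (counts to integers, minute totals and currency to the nearest 1,000,
# QALYs to one decimal) is applied only in the reported values and never
# feeds back into the computation.

#' Default QALY gain per additional minute of vigorous activity
#'
#' The canonical coefficient 0.0000074 QALY/minute, obtained from an
#' estimated 0.0106768 QALYs for 30 additional weekly minutes sustained
#' over a 48-week year; see [qaly_per_minute_from_block()].
#' @export
QALY_PER_MINUTE <- 0.0000074

#' Default monetary reference values per QALY
#'
#' EUR 20,000 (the common cost-effectiveness threshold, e.g. NICE's
#' range) and EUR 80,000 (the Dutch reference value for the maximum
#' spend per QALY).
#' @export
DEFAULT_THRESHOLDS <- c(20000, 80000)

present_count <- function(x) round(x)
present_thousand <- function(x) 1000 * round(x / 1000)
present_qaly <- function(x) round(x, 1)

#' Aggregate framework inputs
#'
#' Bundles the six aggregate parameters of the impact chain — event
#' participants (A), the fraction who performed additional vigorous
#' training (B), the fraction of those initially below the WHO vigorous
#' guideline (C), the mean preparation duration in weeks (D), and the
#' mean weekly vigorous-PA minutes without (E) and during (F) the
#' preparation — together with the QALY coefficient and the monetary
#' thresholds.
#'
#' The per-participant additional minutes default to `D * (F - E)`
#' (product of means). When per-participant totals are available their
#' mean (`mean_additional_total`) can be supplied instead; it then takes
#' precedence, because the mean of per-participant products differs from
#' the product of means when preparation length and weekly minutes
#' covary. Both values are carried in the result so the difference stays
#' visible.
#'
#' @param participants Number of event participants (A).
#' @param p_extra Fraction performing additional preparation PA (B).
#' @param p_inactive Fraction of extra trainers initially not meeting the
#'   WHO vigorous guideline (C).
#' @param prep_weeks Mean preparation duration in weeks (D).
#' @param cf_min_per_week Mean counterfactual vigorous PA in minutes/week
#'   (E).
#' @param prep_min_per_week Mean preparation vigorous PA in minutes/week
#'   (F).
#' @param mean_additional_total Optional mean per-participant total
#'   additional minutes; overrides `prep_weeks * (prep_min_per_week -
#'   cf_min_per_week)` when supplied.
#' @param qaly_per_minute QALY gain per additional minute of vigorous PA
#'   (default [QALY_PER_MINUTE]).
#' @param thresholds Monetary reference values per QALY (default
#'   [DEFAULT_THRESHOLDS]).
#' @param currency Currency label for reporting (default `"EUR"`).
#' @return Object of class `framework_inputs`.
#' @seealso [run_framework()], [marikenloop_framework_inputs()]
#' @export
framework_inputs <- function(participants, p_extra, p_inactive,
                             prep_weeks = NULL, cf_min_per_week = NULL,
                             prep_min_per_week = NULL,
                             mean_additional_total = NULL,
                             qaly_per_minute = QALY_PER_MINUTE,
                             thresholds = DEFAULT_THRESHOLDS,
                             currency = "EUR") {
  stopifnot(
    length(participants) == 1L, participants >= 0,
    length(p_extra) == 1L, p_extra >= 0, p_extra <= 1,
    length(p_inactive) == 1L, p_inactive >= 0, p_inactive <= 1,
    qaly_per_minute > 0, length(thresholds) >= 1L, all(thresholds > 0)
  )
  has_chain <- !is.null(prep_weeks) && !is.null(cf_min_per_week) &&
    !is.null(prep_min_per_week)
  if (!has_chain && is.null(mean_additional_total)) {
    stop("supply either mean_additional_total or all of prep_weeks, ",
         "cf_min_per_week and prep_min_per_week", call. = FALSE)
  }
  if (has_chain) {
    stopifnot(prep_weeks > 0, cf_min_per_week >= 0, prep_min_per_week >= 0)
  }
  structure(list(
    participants = participants, p_extra = p_extra,
    p_inactive = p_inactive, prep_weeks = prep_weeks,
    cf_min_per_week = cf_min_per_week,
    prep_min_per_week = prep_min_per_week,
    mean_additional_total = mean_additional_total,
    qaly_per_minute = qaly_per_minute,
    thresholds = sort(thresholds), currency = currency
  ), class = "framework_inputs")
}

#' Marikenloop 2017 framework preset
#'
#' The aggregate parameterization of the 2017 Marikenloop women-only
#' running event: 7304 participants, 32% extra trainers, 68% of them
#' initially inactive, 8.8 preparation weeks, 64 counterfactual and 127
#' preparation minutes/week, and a mean per-participant additional total
#' of 565 minutes (the survey mean of per-participant totals, which the
#' headline chain uses in place of the 8.8 x 63 = 554.4 product of
#' means).
#'
#' @return A `framework_inputs` object.
#' @examples
#' run_framework(marikenloop_framework_inputs())
#' @export
marikenloop_framework_inputs <- function() {
  framework_inputs(
    participants = 7304, p_extra = 0.32, p_inactive = 0.68,
    prep_weeks = 8.8, cf_min_per_week = 64, prep_min_per_week = 127,
    mean_additional_total = 565
  )
}

#' Initially inactive participant count
#'
#' `A x B x C`: participants times the extra-training fraction times the
#' initially-inactive fraction, rounded to the nearest integer for
#' reporting; the unrounded value is kept in the `"raw"` attribute.
#'
#' @inheritParams framework_inputs
#' @return Rounded count with attribute `raw`.
#' @examples
#' compute_inactive_count(7304, 0.32, 0.68)
#' @export
compute_inactive_count <- function(participants, p_extra, p_inactive) {
  stopifnot(participants >= 0, p_extra >= 0, p_extra <= 1,
            p_inactive >= 0, p_inactive <= 1)
  raw <- participants * p_extra * p_inactive
  structure(present_count(raw), raw = raw)
}

#' Mean additional minutes per participant
#'
#' `D * (F - E)`: preparation weeks times the difference between weekly
#' preparation and counterfactual minutes. May be negative when the
#' counterfactual exceeds the preparation level; how to handle that is
#' left to the caller ([run_framework()] floors it at zero with a
#' warning).
#'
#' @inheritParams framework_inputs
#' @return Minutes (numeric scalar).
#' @examples
#' additional_minutes_per_participant(8.8, 64, 127)
#' @export
additional_minutes_per_participant <- function(prep_weeks, cf_min_per_week,
                                               prep_min_per_week) {
  if (prep_weeks <= 0) stop("prep_weeks must be positive", call. = FALSE)
  stopifnot(cf_min_per_week >= 0, prep_min_per_week >= 0)
  prep_weeks * (prep_min_per_week - cf_min_per_week)
}

#' Total additional vigorous minutes (G)
#'
#' @param n_inactive Number of initially inactive extra trainers.
#' @param per_participant Mean additional minutes per such participant.
#' @return Raw total minutes, with attribute `presented` rounded to the
#'   nearest 1,000 for reporting.
#' @examples
#' total_additional_minutes(1589, 565)
#' @export
total_additional_minutes <- function(n_inactive, per_participant) {
  stopifnot(n_inactive >= 0)
  raw <- n_inactive * per_participant
  structure(raw, presented = present_thousand(raw))
}

#' Convert additional minutes to QALYs (H)
#'
#' `H = G x q`, with q the QALY gain per additional vigorous minute.
#' Reported to one decimal; the raw value is returned.
#'
#' @param total_minutes Total additional vigorous minutes (G).
#' @param qaly_per_minute QALY/minute coefficient (default
#'   [QALY_PER_MINUTE]).
#' @return Raw QALYs, with attribute `presented` rounded to 1 decimal.
#' @examples
#' minutes_to_qalys(898000)
#' @export
minutes_to_qalys <- function(total_minutes,
                             qaly_per_minute = QALY_PER_MINUTE) {
  stopifnot(total_minutes >= 0, qaly_per_minute > 0)
  raw <- total_minutes * qaly_per_minute
  structure(raw, presented = present_qaly(raw))
}

#' Derive the QALY-per-minute coefficient from a weekly block estimate
#'
#' Health-economic estimates of the QALY gain from physical activity are
#' typically stated per weekly block (e.g. 0.0106768 QALYs for 30
#' additional minutes per week sustained over a year of 48 weeks, i.e.
#' 12 months of 4 weeks). Dividing by the total minutes in the block
#' gives the per-minute coefficient; the canonical constant rounds it to
#' 7 decimals.
#'
#' @param qaly_per_block QALY gain for the weekly block over a year.
#' @param block_min_per_week Minutes per week in the block (default 30).
#' @param weeks_per_year Weeks counted per year (default 48).
#' @param digits Decimals for the canonical rounding (default 7).
#' @return Rounded coefficient with attribute `raw` (unrounded).
#' @examples
#' qaly_per_minute_from_block(0.0106768)
#' @export
qaly_per_minute_from_block <- function(qaly_per_block,
                                       block_min_per_week = 30,
                                       weeks_per_year = 48, digits = 7) {
  stopifnot(qaly_per_block > 0, block_min_per_week > 0, weeks_per_year > 0)
  raw <- qaly_per_block / (block_min_per_week * weeks_per_year)
  structure(round(raw, digits), raw = raw)
}

#' Monetize QALYs against reference thresholds (I)
#'
#' `I[v] = H x v` for each monetary reference value v per QALY; reported
#' to the nearest 1,000 currency units.
#'
#' @param qalys QALYs gained (H), raw (unrounded) value.
#' @param thresholds Monetary reference values per QALY.
#' @return Named numeric vector of raw monetary values, with attribute
#'   `presented` rounded to the nearest 1,000.
#' @examples
#' monetize(6.6452, c(20000, 80000))
#' @export
monetize <- function(qalys, thresholds = DEFAULT_THRESHOLDS) {
  stopifnot(qalys >= 0, length(thresholds) >= 1L)
  raw <- qalys * thresholds
  names(raw) <- as.character(thresholds)
  structure(raw, presented = present_thousand(raw))
}

# Assemble a framework_result from raw chain values.
build_framework_result <- function(inputs, n_inactive_raw, per_week,
                                   per_participant_formula,
                                   per_participant_used, n_floored = 0L,
                                   derived_inputs = NULL,
                                   cohort_n = NULL) {
  g_raw <- n_inactive_raw * per_participant_used
  h_raw <- g_raw * inputs$qaly_per_minute
  i_raw <- h_raw * inputs$thresholds
  names(i_raw) <- as.character(inputs$thresholds)

  presented <- list(
    n_inactive = present_count(n_inactive_raw),
    additional_min_per_week = per_week,
    additional_min_per_participant = per_participant_used,
    total_additional_minutes = present_thousand(g_raw),
    qalys = present_qaly(h_raw),
    monetary_value = present_thousand(i_raw)
  )
  rounding_report <- data.frame(
    quantity = c("n_inactive", "total_additional_minutes", "qalys",
                 paste0("monetary_value_", names(i_raw))),
    raw = c(n_inactive_raw, g_raw, h_raw, unname(i_raw)),
    presented = c(presented$n_inactive, presented$total_additional_minutes,
                  presented$qalys, unname(presented$monetary_value)),
    stringsAsFactors = FALSE
  )
  structure(list(
    inputs = inputs,
    n_inactive = n_inactive_raw,
    additional_min_per_week = per_week,
    additional_min_per_participant_formula = per_participant_formula,
    additional_min_per_participant = per_participant_used,
    total_additional_minutes = g_raw,
    qalys = h_raw,
    monetary_value = i_raw,
    presented = presented,
    rounding_report = rounding_report,
    n_floored = n_floored,
    derived_inputs = derived_inputs,
    cohort_n = cohort_n
  ), class = "framework_result")
}

#' Run the health-impact chain on aggregate inputs
#'
#' Chains the framework end to end: initially inactive count, total
#' additional vigorous minutes G, QALYs H, and monetary value I at every
#' threshold. All intermediate values are carried unrounded; the
#' `presented` element and the `rounding_report` hold the reporting
#' conventions (counts to integers, minutes and currency to the nearest
#' 1,000, QALYs to one decimal). When `mean_additional_total` is present
#' it is used for the per-participant minutes, and the `D * (F - E)`
#' value is reported alongside. A negative per-participant value is
#' floored at zero with a warning, since the framework only values
#' additional activity.
#'
#' @param inputs A `framework_inputs` object.
#' @return Object of class `framework_result`; see
#'   [build_framework_result] fields: raw chain values, `presented`,
#'   `rounding_report`.
#' @examples
#' res <- run_framework(marikenloop_framework_inputs())
#' res$presented$qalys
#' @export
run_framework <- function(inputs) {
  stopifnot(inherits(inputs, "framework_inputs"))
  has_chain <- !is.null(inputs$prep_weeks)
  per_week <- if (has_chain) {
    inputs$prep_min_per_week - inputs$cf_min_per_week
  } else {
    NA_real_
  }
  per_participant_formula <- if (has_chain) {
    additional_minutes_per_participant(inputs$prep_weeks,
                                       inputs$cf_min_per_week,
                                       inputs$prep_min_per_week)
  } else {
    NA_real_
  }
  per_participant <- if (!is.null(inputs$mean_additional_total)) {
    inputs$mean_additional_total
  } else {
    per_participant_formula
  }
  n_floored <- 0L
  if (per_participant < 0) {
    warning("negative per-participant additional minutes floored at 0",
            call. = FALSE)
    per_participant <- 0
    n_floored <- 1L
  }
  n_inactive_raw <- inputs$participants * inputs$p_extra *
    inputs$p_inactive
  build_framework_result(inputs, n_inactive_raw, per_week,
                         per_participant_formula, per_participant,
                         n_floored = n_floored)
}

#' Run the health-impact chain from participant records
#'
#' Derives the framework quantities from a survey cohort: B is the
#' extra-training fraction, C the initially-inactive fraction among
#' extra trainers, and the total additional minutes are summed over the
#' initially inactive extra trainers record by record (mean of
#' per-participant products, not product of means). Negative per-record
#' totals are floored at zero and counted. When `participants` is given,
#' the cohort is treated as a sample of that population and the total is
#' scaled by `participants / nrow(records)`.
#'
#' @param records A validated cohort data frame.
#' @param participants Optional full-event participant count (A);
#'   defaults to the cohort size (no scaling).
#' @param qaly_per_minute QALY/minute coefficient.
#' @param thresholds Monetary reference values per QALY.
#' @param who_threshold WHO vigorous guideline in minutes/week.
#' @param currency Currency label.
#' @return A `framework_result` whose `derived_inputs` element holds the
#'   `framework_inputs` estimated from the cohort and whose `n_floored`
#'   counts the records floored at zero.
#' @examples
#' cohort <- generate_cohort(marikenloop_preset())
#' res <- run_framework_from_records(cohort, participants = 7304)
#' res$presented$qalys
#' @export
run_framework_from_records <- function(records, participants = NULL,
                                       qaly_per_minute = QALY_PER_MINUTE,
                                       thresholds = DEFAULT_THRESHOLDS,
                                       who_threshold = 75,
                                       currency = "EUR") {
  stopifnot(is.data.frame(records))
  n <- nrow(records)
  if (n == 0L) stop("empty cohort", call. = FALSE)
  if (is.null(participants)) participants <- n
  full <- add_derived(records, who_threshold)

  extra <- full$extra_training %in% TRUE
  if (!any(extra)) stop("no extra-training records", call. = FALSE)
  p_extra <- mean(extra)
  inactive <- extra & full$initially_inactive %in% TRUE
  p_inactive <- sum(inactive) / sum(extra)

  totals <- full$additional_min_total[inactive]
  n_floored <- sum(totals < 0)
  if (n_floored > 0L) {
    warning(n_floored, " record(s) with negative additional minutes ",
            "floored at 0", call. = FALSE)
  }
  totals <- pmax(totals, 0)

  scale <- participants / n
  g_cohort <- sum(totals)
  mean_total <- if (length(totals) > 0L) mean(totals) else 0

  derived_inputs <- framework_inputs(
    participants = participants, p_extra = p_extra,
    p_inactive = p_inactive,
    prep_weeks = if (any(inactive)) mean(full$prep_weeks[inactive]) else NULL,
    cf_min_per_week = if (any(inactive)) {
      mean(full$weekly_min_cf[inactive])
    } else {
      NULL
    },
    prep_min_per_week = if (any(inactive)) {
      mean(full$weekly_min_prep[inactive])
    } else {
      NULL
    },
    mean_additional_total = mean_total,
    qaly_per_minute = qaly_per_minute, thresholds = thresholds,
    currency = currency
  )
  per_week <- if (any(inactive)) {
    mean(full$additional_min_per_week[inactive])
  } else {
    0
  }
  per_participant_formula <- if (any(inactive)) {
    mean(full$prep_weeks[inactive]) * per_week
  } else {
    0
  }
  # Chain from the scaled per-record sum: A x B x C x mean_total equals
  # scale x sum(totals) exactly, so carry the latter.
  n_inactive_raw <- participants * p_extra * p_inactive
  result <- build_framework_result(
    derived_inputs, n_inactive_raw, per_week, per_participant_formula,
    mean_total, n_floored = n_floored, derived_inputs = derived_inputs,
    cohort_n = n
  )
  # Guard: the assembled G must equal the scaled cohort sum.
  stopifnot(abs(result$total_additional_minutes - scale * g_cohort) <
              1e-6 * max(1, scale * g_cohort))
  result
}

#' Sensitivity sweep over monetary thresholds
#'
#' Evaluates the monetary value I over a grid of reference values per
#' QALY, holding the rest of the chain fixed.
#'
#' @param inputs A `framework_inputs` object.
#' @param v_grid Numeric vector of thresholds (currency per QALY).
#' @return Data frame with columns `threshold`, `value_raw`,
#'   `value_presented` (nearest 1,000), monotone non-decreasing in
#'   `threshold`.
#' @examples
#' threshold_sweep(marikenloop_framework_inputs(), c(20000, 50000, 80000))
#' @export
threshold_sweep <- function(inputs, v_grid) {
  stopifnot(inherits(inputs, "framework_inputs"), length(v_grid) >= 1L,
            all(v_grid > 0))
  res <- run_framework(inputs)
  v_grid <- sort(v_grid)
  raw <- res$qalys * v_grid
  data.frame(threshold = v_grid, value_raw = raw,
             value_presented = present_thousand(raw))
}

#' @export
print.framework_result <- function(x, ...) {
  p <- x$presented
  cur <- x$inputs$currency
  cat("MPSE health-impact framework result\n")
  if (!is.null(x$cohort_n)) {
    cat(sprintf("  derived from a cohort of %d records (scaled to %s participants)\n",
                x$cohort_n, format(x$inputs$participants, big.mark = ",")))
  }
  cat(sprintf("  participants (A):                %s\n",
              format(x$inputs$participants, big.mark = ",")))
  cat(sprintf("  extra-training fraction (B):     %.3f\n", x$inputs$p_extra))
  cat(sprintf("  initially inactive fraction (C): %.3f\n",
              x$inputs$p_inactive))
  cat(sprintf("  initially inactive count:        %s\n",
              format(p$n_inactive, big.mark = ",")))
  if (!is.na(x$additional_min_per_week)) {
    cat(sprintf("  additional PA per week (F - E):  %.1f min\n",
                x$additional_min_per_week))
  }
  cat(sprintf("  additional PA per participant:   %.1f min\n",
              x$additional_min_per_participant))
  cat(sprintf("  total additional PA (G):         %s min\n",
              format(p$total_additional_minutes, big.mark = ",",
                     scientific = FALSE)))
  cat(sprintf("  QALYs gained (H):                %.1f\n", p$qalys))
  for (v in names(x$monetary_value)) {
    cat(sprintf("  monetary value at %s %s/QALY: %s %s\n", cur,
                format(as.numeric(v), big.mark = ",", scientific = FALSE),
                cur,
                format(p$monetary_value[[v]], big.mark = ",",
                       scientific = FALSE)))
  }
  if (x$n_floored > 0L) {
    cat(sprintf("  (%d record(s)/value(s) floored at 0 additional minutes)\n",
                x$n_floored))
  }
  invisible(x)
}

#' Export a framework result as JSON
#'
#' Writes a versioned report holding the raw chain values, the presented
#' (rounded) values and the rounding report.
#'
#' @param result A `framework_result`.
#' @param path Output JSON path; when `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to file).
#' @export
framework_report_json <- function(result, path = NULL) {
  stopifnot(inherits(result, "framework_result"))
  payload <- list(
    schema_version = "1.0",
    inputs = Filter(Negate(is.null), unclass(result$inputs)),
    raw = list(
      n_inactive = result$n_inactive,
      additional_min_per_week = result$additional_min_per_week,
      additional_min_per_participant =
        result$additional_min_per_participant,
      additional_min_per_participant_formula =
        result$additional_min_per_participant_formula,
      total_additional_minutes = result$total_additional_minutes,
      qalys = result$qalys,
      monetary_value = as.list(result$monetary_value)
    ),
    presented = list(
      n_inactive = result$presented$n_inactive,
      total_additional_minutes =
        result$presented$total_additional_minutes,
      qalys = result$presented$qalys,
      monetary_value = as.list(result$presented$monetary_value)
    ),
    rounding_report = result$rounding_report,
    n_floored = result$n_floored,
    cohort_n = result$cohort_n
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           null = "null")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' Read framework inputs from a YAML config
#'
#' Keys match the arguments of [framework_inputs()].
#'
#' @param path YAML file path.
#' @return A `framework_inputs` object.
#' @export
framework_inputs_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(framework_inputs))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    stop("unknown framework input(s) in YAML: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(framework_inputs, raw)
}
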