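# Applying a chart to timestamped observation series.
#
# Observation values travel as character strings internally (one CSV column
# holds continuous and categorical measurements alike); they are coerced per
# the chart parameter's kind at classification time.

#' One patient's monitored series plus outcome label
#'
#' @param patient_id Patient identifier (coerced to character).
#' @param observations A data.frame with columns `time_h` (numeric hours from
#'   enrolment), `parameter`, `value`. Not every parameter need be measured
#'   at every round; laboratory parameters are typically measured once.
#' @param delivery_time_h Delivery time in hours from enrolment.
#' @param outcome Morbidity category: `1` (no obstetric morbidity during the
#'   hospital stay) or `2` (morbidity during the stay). `NA` allowed for
#'   scoring-only use; evaluation requires a label.
#' @param delivery_mode Optional: `"normal"`, `"lscs"` or `"assisted"`.
#' @return An object of class `"patient_record"`.
#' @export
patient_record <- function(patient_id, observations, delivery_time_h = NA_real_,
                           outcome = NA_integer_, delivery_mode = NA_character_) {
  stopifnot(length(patient_id) == 1L, is.data.frame(observations),
            all(c("time_h", "parameter", "value") %in% names(observations)))
  obs <- data.frame(time_h = as.numeric(observations$time_h),
                    parameter = as.character(observations$parameter),
                    value = as.character(observations$value),
                    stringsAsFactors = FALSE)
  if (nrow(obs) == 0L) stop("patient ", patient_id, ": no observations")
  if (anyNA(obs$time_h) || any(!is.finite(obs$time_h))) {
    stop("patient ", patient_id, ": non-finite observation times")
  }
  times <- unique(obs$time_h)
  if (is.unsorted(times, strictly = TRUE)) {
    stop("patient ", patient_id,
         ": observation rounds must be strictly increasing in time")
  }
  if (anyDuplicated(obs[c("time_h", "parameter")])) {
    stop("patient ", patient_id,
         ": duplicate parameter measurement within one round")
  }
  outcome <- as.integer(outcome)
  if (!is.na(outcome) && !outcome %in% c(1L, 2L)) {
    stop("patient ", patient_id, ": outcome must be 1 or 2")
  }
  if (!is.na(delivery_mode)) {
    delivery_mode <- match.arg(delivery_mode, c("normal", "lscs", "assisted"))
  }
  structure(list(patient_id = as.character(patient_id), observations = obs,
                 delivery_time_h = as.numeric(delivery_time_h),
                 outcome = outcome, delivery_mode = delivery_mode),
            class = "patient_record")
}

#' @export
print.patient_record <- function(x, ...) {
  cat("<patient_record> ", x$patient_id, ": ",
      length(unique(x$observations$time_h)), " rounds, ",
      nrow(x$observations), " measurements; delivery at ",
      x$delivery_time_h, " h; outcome category ", x$outcome, "\n", sep = "")
  invisible(x)
}

coerce_value <- function(spec, value) {
  if (spec$kind == "continuous") {
    v <- suppressWarnings(as.numeric(value))
    if (is.na(v)) {
      stop("parameter '", spec$name, "': non-numeric value '", value, "'")
    }
    v
  } else {
    as.character(value)
  }
}

#' Score one observation round against a chart
#'
#' Classifies every supplied value into its zone and applies the chart's
#' trigger rule to the round. Parameters the round does not measure
#' contribute nothing and are listed as unmeasured.
#'
#' @param chart An `mms_chart`.
#' @param values Named list or vector: parameter name -> measurement.
#' @param unknown_parameters `"error"` (default) to reject values for
#'   parameters the chart does not monitor, or `"ignore"` to skip them
#'   (useful when scoring a cohort under a comparator chart that monitors a
#'   subset of the recorded parameters).
#' @return A list: `zones` (named character), `n_red`, `n_orange`,
#'   `trigger` (logical), `unmeasured` (chart parameters absent from the
#'   round), `skipped` (values ignored under `"ignore"`).
#' @examples
#' score_observation(mms_chart(), list(heart_rate = 110, rbs = 250))
#' @export
score_observation <- function(chart, values,
                              unknown_parameters = c("error", "ignore")) {
  stopifnot(inherits(chart, "mms_chart"))
  unknown_parameters <- match.arg(unknown_parameters)
  nms <- names(values)
  if (length(values) == 0L || is.null(nms) || any(!nzchar(nms))) {
    stop("values must be a non-empty named list")
  }
  if (anyDuplicated(nms)) stop("duplicate parameter in observation")

  unknown <- setdiff(nms, chart_parameters(chart))
  if (length(unknown) && unknown_parameters == "error") {
    stop("chart '", chart$name, "' does not monitor: ",
         paste(unknown, collapse = ", "))
  }
  keep <- setdiff(nms, unknown)
  zones <- vapply(keep, function(p) {
    spec <- chart_parameter(chart, p)
    classify_value(spec, coerce_value(spec, values[[p]]))
  }, character(1))

  n_red <- sum(zones == "red")
  n_orange <- sum(zones == "orange")
  rule <- chart$trigger_rule
  list(zones = zones,
       n_red = n_red, n_orange = n_orange,
       trigger = n_red >= rule$red || n_orange >= rule$orange,
       unmeasured = setdiff(chart_parameters(chart), keep),
       skipped = unknown)
}

#' Evaluate a patient's full monitored series
#'
#' Scores every observation round, dichotomises the patient into the
#' triggered / non-triggered group (triggered if any single round fires the
#' chart's trigger rule), and records the first trigger time and the worst
#' zone each parameter attained across the series.
#'
#' @param chart An `mms_chart`.
#' @param record A [patient_record()].
#' @param unknown_parameters Passed to [score_observation()].
#' @return An object of class `"trigger_summary"`: a list with
#'   `patient_id`, `triggered`, `first_trigger_time_h` (`NA` when never
#'   triggered), `zones` (data.frame `time_h`, `parameter`, `zone`),
#'   `rounds` (data.frame `time_h`, `n_red`, `n_orange`, `trigger`) and
#'   `per_parameter_worst` (named character).
#' @export
evaluate_patient <- function(chart, record,
                             unknown_parameters = c("error", "ignore")) {
  stopifnot(inherits(chart, "mms_chart"), inherits(record, "patient_record"))
  unknown_parameters <- match.arg(unknown_parameters)
  obs <- record$observations
  times <- unique(obs$time_h)

  zone_rows <- vector("list", length(times))
  round_rows <- vector("list", length(times))
  for (i in seq_along(times)) {
    t <- times[i]
    sel <- obs[obs$time_h == t, , drop = FALSE]
    values <- as.list(sel$value); names(values) <- sel$parameter
    sc <- tryCatch(
      score_observation(chart, values, unknown_parameters),
      error = function(e) {
        stop("patient ", record$patient_id, ", t = ", t, " h: ",
             conditionMessage(e), call. = FALSE)
      })
    if (length(sc$zones)) {
      zone_rows[[i]] <- data.frame(time_h = t, parameter = names(sc$zones),
                                   zone = unname(sc$zones),
                                   stringsAsFactors = FALSE)
    }
    round_rows[[i]] <- data.frame(time_h = t, n_red = sc$n_red,
                                  n_orange = sc$n_orange, trigger = sc$trigger)
  }
  zones <- do.call(rbind, zone_rows[!vapply(zone_rows, is.null, logical(1))])
  rounds <- do.call(rbind, round_rows)
  triggered <- any(rounds$trigger)
  first_t <- if (triggered) min(rounds$time_h[rounds$trigger]) else NA_real_

  worst <- if (is.null(zones) || nrow(zones) == 0L) {
    stats::setNames(character(0), character(0))
  } else {
    vapply(split(zones$zone, zones$parameter), worst_zone, character(1))
  }

  structure(list(patient_id = record$patient_id, triggered = triggered,
                 first_trigger_time_h = first_t, zones = zones,
                 rounds = rounds, per_parameter_worst = worst,
                 chart = chart$name),
            class = "trigger_summary")
}

#' @export
print.trigger_summary <- function(x, ...) {
  cat("<trigger_summary> ", x$patient_id, " [", x$chart, "]: ",
      if (x$triggered) paste0("TRIGGERED at ", x$first_trigger_time_h, " h")
      else "not triggered", "\n", sep = "")
  abn <- x$per_parameter_worst[x$per_parameter_worst != "green"]
  if (length(abn)) {
    cat("  worst alert zones: ",
        paste(names(abn), abn, sep = "=", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Evaluate every patient in a cohort
#'
#' @param chart An `mms_chart`.
#' @param cohort List of [patient_record()] objects.
#' @param unknown_parameters Passed to [score_observation()].
#' @return List of `trigger_summary` objects, named by patient id.
#' @export
evaluate_cohort <- function(chart, cohort,
                            unknown_parameters = c("error", "ignore")) {
  stopifnot(is.list(cohort), length(cohort) > 0L)
  unknown_parameters <- match.arg(unknown_parameters)
  out <- lapply(cohort, evaluate_patient, chart = chart,
                unknown_parameters = unknown_parameters)
  names(out) <- vapply(out, `[[`, character(1), "patient_id")
  if (anyDuplicated(names(out))) stop("duplicate patient ids in cohort")
  out
}

#' Check a record against the 4-hourly peripartum monitoring schedule
#'
#' The study design monitors every `interval` hours from enrolment until
#' `horizon_after_delivery` hours after delivery. This report is advisory:
#' deviations never block scoring.
#'
#' @param record A [patient_record()].
#' @param interval Monitoring interval in hours (default 4).
#' @param horizon_after_delivery Hours of post-delivery monitoring
#'   (default 24).
#' @param tol Matching tolerance in hours between an expected round and the
#'   nearest observed time.
#' @return A list: `expected_times`, `observed_times`, `missing_times`,
#'   `gaps` (data.frame of consecutive observed times more than `interval`
#'   apart), `beyond_horizon` (observed times after delivery + horizon) and
#'   `compliant` (no missing rounds, no gaps, nothing beyond horizon).
#' @export
check_schedule <- function(record, interval = 4, horizon_after_delivery = 24,
                           tol = 0.5) {
  stopifnot(inherits(record, "patient_record"), interval > 0,
            horizon_after_delivery >= 0)
  observed <- unique(record$observations$time_h)
  end <- if (is.na(record$delivery_time_h)) max(observed)
         else record$delivery_time_h + horizon_after_delivery
  expected <- seq(0, end, by = interval)
  missing <- expected[vapply(expected,
                             function(t) !any(abs(observed - t) <= tol),
                             logical(1))]
  dt <- diff(observed)
  gap_idx <- which(dt > interval + tol)
  gaps <- data.frame(from_h = observed[gap_idx], to_h = observed[gap_idx + 1L],
                     gap_h = dt[gap_idx])
  beyond <- observed[observed > end + tol]
  list(expected_times = expected, observed_times = observed,
       missing_times = missing, gaps = gaps, beyond_horizon = beyond,
       compliant = length(missing) == 0L && nrow(gaps) == 0L &&
         length(beyond) == 0L)
}

#' Cohort-level trigger and abnormality summary
#'
#' Counts and percentages of triggered vs non-triggered patients, plus a
#' per-parameter tally of patients whose worst zone over the whole series
#' was orange, red, and orange+red combined (the abnormal-zone tally shape
#' of the published per-parameter tables).
#'
#' @param chart An `mms_chart`.
#' @param cohort List of [patient_record()] objects, or a pre-computed list
#'   of `trigger_summary` objects.
#' @param unknown_parameters Passed to [score_observation()].
#' @return An object of class `"cohort_summary"`: a list with `chart`, `n`,
#'   `n_triggered`, `n_non_triggered`, `pct_triggered`, `pct_non_triggered`
#'   and `parameter_table` (data.frame `parameter`, `green`, `orange`,
#'   `red`, `abnormal`, `abnormal_pct`).
#' @export
cohort_summary <- function(chart, cohort,
                           unknown_parameters = c("error", "ignore")) {
  stopifnot(is.list(cohort), length(cohort) > 0L)
  summaries <- if (all(vapply(cohort, inherits, logical(1), "trigger_summary")))
    cohort
  else
    evaluate_cohort(chart, cohort, match.arg(unknown_parameters))

  n <- length(summaries)
  trig <- vapply(summaries, `[[`, logical(1), "triggered")
  params <- chart_parameters(chart)
  tally <- t(vapply(params, function(p) {
    worst <- vapply(summaries, function(s) {
      w <- s$per_parameter_worst[[p]]
      if (is.null(w)) NA_character_ else w
    }, character(1))
    c(green = sum(worst == "green", na.rm = TRUE),
      orange = sum(worst == "orange", na.rm = TRUE),
      red = sum(worst == "red", na.rm = TRUE))
  }, numeric(3)))
  parameter_table <- data.frame(
    parameter = params,
    green = tally[, "green"], orange = tally[, "orange"], red = tally[, "red"],
    abnormal = tally[, "orange"] + tally[, "red"],
    abnormal_pct = (tally[, "orange"] + tally[, "red"]) / n * 100,
    row.names = NULL, stringsAsFactors = FALSE)

  structure(list(chart = chart$name, n = n,
                 n_triggered = sum(trig), n_non_triggered = sum(!trig),
                 pct_triggered = sum(trig) / n * 100,
                 pct_non_triggered = sum(!trig) / n * 100,
                 parameter_table = parameter_table),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, digits = 2, ...) {
  cat("<cohort_summary> chart ", x$chart, ", n = ", x$n, "\n", sep = "")
  cat("  triggered:     ", x$n_triggered, " (",
      round(x$pct_triggered, digits), "%)\n", sep = "")
  cat("  non-triggered: ", x$n_non_triggered, " (",
      round(x$pct_non_triggered, digits), "%)\n", sep = "")
  abn <- x$parameter_table[x$parameter_table$abnormal > 0, , drop = FALSE]
  if (nrow(abn)) {
    cat("  abnormal-zone patients by parameter:\n")
    for (i in seq_len(nrow(abn))) {
      cat("   - ", abn$parameter[i], ": ", abn$abnormal[i], " (",
          round(abn$abnormal_pct[i], digits), "%)\n", sep = "")
    }
  }
  invisible(x)
}
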