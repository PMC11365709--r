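# Diagnostic accuracy of trigger status against morbidity outcome.
# Screen-positive = triggered; disease-positive = outcome category 2
# (obstetric morbidity during the hospital stay).

#' 2x2 screening contingency table
#'
#' @param tp Triggered and category 2 (true positives).
#' @param fp Triggered and category 1 (false positives).
#' @param fn Non-triggered and category 2 (false negatives).
#' @param tn Non-triggered and category 1 (true negatives).
#' @return An object of class `"contingency_2x2"`.
#' @export
contingency_2x2 <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    stop("contingency counts must be non-negative integers")
  }
  if (sum(counts) == 0) stop("contingency table is empty")
  counts <- as.integer(counts)
  structure(list(tp = counts[1], fp = counts[2], fn = counts[3],
                 tn = counts[4]),
            class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(c("triggered", "non-triggered"),
                              c("category2", "category1")))
  cat("<contingency_2x2> n =", sum(unlist(x)), "\n")
  print(m)
  invisible(x)
}

#' @export
as.matrix.contingency_2x2 <- function(x, ...) {
  matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
         dimnames = list(c("triggered", "non-triggered"),
                         c("category2", "category1")))
}

#' Build the 2x2 table from trigger summaries and outcome labels
#'
#' @param summaries List of `trigger_summary` objects (see
#'   [evaluate_patient()]); patient ids must be unique.
#' @param outcomes Named vector mapping patient id to morbidity category
#'   (1 = no obstetric morbidity during stay, 2 = morbidity), or `NULL` to
#'   look outcomes up from `records`.
#' @param records Optional list of [patient_record()] objects carrying
#'   outcome labels (used when `outcomes` is `NULL`).
#' @return A [contingency_2x2()].
#' @export
build_contingency <- function(summaries, outcomes = NULL, records = NULL) {
  stopifnot(is.list(summaries), length(summaries) > 0L,
            all(vapply(summaries, inherits, logical(1), "trigger_summary")))
  ids <- vapply(summaries, `[[`, character(1), "patient_id")
  if (anyDuplicated(ids)) {
    stop("duplicate patients: ", paste(unique(ids[duplicated(ids)]),
                                       collapse = ", "))
  }
  if (is.null(outcomes)) {
    if (is.null(records)) stop("supply `outcomes` or `records`")
    outcomes <- stats::setNames(
      vapply(records, `[[`, integer(1), "outcome"),
      vapply(records, `[[`, character(1), "patient_id"))
  }
  out <- outcomes[ids]
  if (anyNA(out)) {
    stop("no outcome label for patient(s): ",
         paste(ids[is.na(out)], collapse = ", "))
  }
  if (!all(out %in% c(1, 2))) stop("outcomes must be category 1 or 2")
  trig <- vapply(summaries, `[[`, logical(1), "triggered")
  contingency_2x2(tp = sum(trig & out == 2), fp = sum(trig & out == 1),
                  fn = sum(!trig & out == 2), tn = sum(!trig & out == 1))
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param x Number of successes.
#' @param n Number of trials (`n > 0`).
#' @param level Confidence level (default 0.95).
#' @return Numeric `c(lower, upper)`, as proportions in `[0, 1]`.
#' @export
wilson_ci <- function(x, n, level = 0.95) {
  stopifnot(n > 0, x >= 0, x <= n, level > 0, level < 1)
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Diagnostic accuracy metrics from a 2x2 table
#'
#' Sensitivity, specificity, positive and negative predictive value and
#' overall accuracy, each as a percentage with a Wilson score interval.
#' A metric whose denominator is zero (degenerate cohorts) is reported as
#' `NA` ("undefined") rather than raising an error, so batch evaluation
#' never crashes.
#'
#' @param table A [contingency_2x2()].
#' @param ci_level Confidence level for the Wilson intervals.
#' @return An object of class `"diagnostic_report"`: a list with `metrics`
#'   (data.frame `metric`, `numerator`, `denominator`, `estimate`, `lower`,
#'   `upper`, all estimates in percent), `ci_level` and `counts`.
#' @examples
#' diagnostic_metrics(contingency_2x2(38, 19, 2, 162))
#' @export
diagnostic_metrics <- function(table, ci_level = 0.95) {
  stopifnot(inherits(table, "contingency_2x2"))
  total <- table$tp + table$fp + table$fn + table$tn
  defs <- list(
    sensitivity = c(table$tp, table$tp + table$fn),
    specificity = c(table$tn, table$tn + table$fp),
    ppv         = c(table$tp, table$tp + table$fp),
    npv         = c(table$tn, table$tn + table$fn),
    accuracy    = c(table$tp + table$tn, total))
  rows <- lapply(names(defs), function(m) {
    num <- defs[[m]][1]; den <- defs[[m]][2]
    if (den == 0) {
      data.frame(metric = m, numerator = num, denominator = den,
                 estimate = NA_real_, lower = NA_real_, upper = NA_real_)
    } else {
      ci <- wilson_ci(num, den, ci_level)
      data.frame(metric = m, numerator = num, denominator = den,
                 estimate = num / den * 100,
                 lower = ci[["lower"]] * 100, upper = ci[["upper"]] * 100)
    }
  })
  structure(list(metrics = do.call(rbind, rows), ci_level = ci_level,
                 counts = table),
            class = "diagnostic_report")
}

#' @export
print.diagnostic_report <- function(x, digits = 2, ...) {
  cat("<diagnostic_report> n = ",
      with(x$counts, tp + fp + fn + tn),
      " (", round(100 * x$ci_level), "% Wilson intervals)\n", sep = "")
  m <- x$metrics
  for (i in seq_len(nrow(m))) {
    if (is.na(m$estimate[i])) {
      cat(sprintf("  %-12s undefined (0 denominator)\n", m$metric[i]))
    } else {
      cat(sprintf("  %-12s %6.2f%%  [%.2f, %.2f]  (%d/%d)\n", m$metric[i],
                  m$estimate[i], m$lower[i], m$upper[i],
                  m$numerator[i], m$denominator[i]))
    }
  }
  invisible(x)
}

#' Extract one metric estimate (percent) from a diagnostic report
#' @param report A `diagnostic_report`.
#' @param metric One of `"sensitivity"`, `"specificity"`, `"ppv"`, `"npv"`,
#'   `"accuracy"`.
#' @return The point estimate in percent (`NA` if undefined).
#' @export
report_metric <- function(report, metric) {
  stopifnot(inherits(report, "diagnostic_report"))
  m <- report$metrics
  i <- match(metric, m$metric)
  if (is.na(i)) stop("unknown metric '", metric, "'")
  m$estimate[i]
}

#' Labelled R x C count table
#'
#' @param counts Non-negative integer matrix, at least 2x2.
#' @param row_labels,col_labels Optional dimension labels.
#' @return An integer matrix with dimnames, class `"rxc_table"`.
#' @export
rxc_table <- function(counts, row_labels = NULL, col_labels = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L || ncol(counts) < 2L) {
    stop("table must be at least 2x2")
  }
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (sum(counts) == 0) stop("table is empty")
  storage.mode(counts) <- "integer"
  if (!is.null(row_labels)) rownames(counts) <- row_labels
  if (!is.null(col_labels)) colnames(counts) <- col_labels
  structure(counts, class = c("rxc_table", "matrix", "array"))
}

#' Pearson chi-square test on an R x C table
#'
#' Pearson's chi-square statistic (no continuity correction by default) with
#' `df = (R-1)(C-1)`, the expected-count matrix and a small-cell warning
#' flag when any expected count falls below 5 — common in tables with a
#' sparse category such as assisted delivery.
#'
#' @param x An [rxc_table()] or plain count matrix.
#' @param correct Apply Yates continuity correction (2x2 tables only;
#'   default `FALSE`).
#' @return A list: `statistic`, `df`, `p_value`, `expected`,
#'   `small_cells` (logical), `correct`.
#' @examples
#' chi_square_test(matrix(c(35, 20, 2, 54, 108, 2), nrow = 3))
#' @export
chi_square_test <- function(x, correct = FALSE) {
  if (!inherits(x, "rxc_table")) x <- rxc_table(x)
  if (any(rowSums(x) == 0) || any(colSums(x) == 0)) {
    stop("zero marginal row/column: expected counts undefined")
  }
  ht <- suppressWarnings(
    stats::chisq.test(unclass(x), correct = correct))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value), expected = ht$expected,
       small_cells = any(ht$expected < 5), correct = correct)
}

#' Compare two screening charts on the same cohort
#'
#' Evaluates every patient under both charts, builds both contingency
#' tables against the morbidity outcomes, and reports the two diagnostic
#' reports side by side with per-metric differences (chart A minus chart B)
#' plus per-parameter abnormal-rate differences for the parameters the
#' charts share.
#'
#' @param cohort List of [patient_record()] objects with outcome labels.
#' @param chart_a,chart_b Two `mms_chart` objects.
#' @param ci_level Confidence level passed to [diagnostic_metrics()].
#' @return An object of class `"chart_comparison"`: a list with `report_a`,
#'   `report_b`, `summary_a`, `summary_b`, `deltas` (data.frame `metric`,
#'   `estimate_a`, `estimate_b`, `delta`) and `parameter_deltas`
#'   (data.frame `parameter`, `abnormal_pct_a`, `abnormal_pct_b`,
#'   `difference`).
#' @export
compare_charts <- function(cohort, chart_a, chart_b, ci_level = 0.95) {
  sums_a <- evaluate_cohort(chart_a, cohort, unknown_parameters = "ignore")
  sums_b <- evaluate_cohort(chart_b, cohort, unknown_parameters = "ignore")
  outcomes <- stats::setNames(
    vapply(cohort, `[[`, integer(1), "outcome"),
    vapply(cohort, `[[`, character(1), "patient_id"))
  rep_a <- diagnostic_metrics(build_contingency(sums_a, outcomes), ci_level)
  rep_b <- diagnostic_metrics(build_contingency(sums_b, outcomes), ci_level)
  deltas <- data.frame(metric = rep_a$metrics$metric,
                       estimate_a = rep_a$metrics$estimate,
                       estimate_b = rep_b$metrics$estimate,
                       delta = rep_a$metrics$estimate - rep_b$metrics$estimate)

  sum_a <- cohort_summary(chart_a, sums_a)
  sum_b <- cohort_summary(chart_b, sums_b)
  shared <- intersect(sum_a$parameter_table$parameter,
                      sum_b$parameter_table$parameter)
  pa <- sum_a$parameter_table[match(shared, sum_a$parameter_table$parameter), ]
  pb <- sum_b$parameter_table[match(shared, sum_b$parameter_table$parameter), ]
  parameter_deltas <- data.frame(
    parameter = shared,
    abnormal_pct_a = pa$abnormal_pct, abnormal_pct_b = pb$abnormal_pct,
    difference = pa$abnormal_pct - pb$abnormal_pct,
    row.names = NULL, stringsAsFactors = FALSE)

  structure(list(chart_a = chart_a$name, chart_b = chart_b$name,
                 report_a = rep_a, report_b = rep_b,
                 summary_a = sum_a, summary_b = sum_b,
                 deltas = deltas, parameter_deltas = parameter_deltas),
            class = "chart_comparison")
}

#' @export
print.chart_comparison <- function(x, digits = 2, ...) {
  cat("<chart_comparison> ", x$chart_a, " vs ", x$chart_b, "\n", sep = "")
  d <- x$deltas
  for (i in seq_len(nrow(d))) {
    cat(sprintf("  %-12s %6.2f%%  vs %6.2f%%  (delta %+.2f)\n", d$metric[i],
                d$estimate_a[i], d$estimate_b[i], d$delta[i]))
  }
  invisible(x)
}
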