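# Contingency tables, diagnostic metrics, chi-square, chart comparison.

test_that("build_contingency cross-tabulates trigger status and outcome", {
  mms <- mms_chart()
  cohort <- list(
    make_record("A", overrides = list(`4` = list(rbs = 250)), outcome = 2L),
    make_record("B", overrides = list(`4` = list(hb = 5)), outcome = 1L),
    make_record("C", outcome = 2L),
    make_record("D", outcome = 1L))
  tab <- build_contingency(evaluate_cohort(mms, cohort),
                           outcomes = outcomes_of(cohort))
  expect_identical(unlist(tab), c(tp = 1L, fp = 1L, fn = 1L, tn = 1L))

  # outcomes can come straight from the records
  tab2 <- build_contingency(evaluate_cohort(mms, cohort), records = cohort)
  expect_identical(unlist(tab2), unlist(tab))

  # all non-triggered, no morbidity
  quiet <- list(make_record("Q1"), make_record("Q2"))
  t0 <- build_contingency(evaluate_cohort(mms, quiet),
                          outcomes = c(Q1 = 1, Q2 = 1))
  expect_identical(unlist(t0), c(tp = 0L, fp = 0L, fn = 0L, tn = 2L))

  # single triggered morbid patient
  one <- list(make_record("X", overrides = list(`0` = list(spo2 = 90)),
                          outcome = 2L))
  t1 <- build_contingency(evaluate_cohort(mms, one), outcomes = c(X = 2))
  expect_identical(unlist(t1), c(tp = 1L, fp = 0L, fn = 0L, tn = 0L))

  expect_error(build_contingency(evaluate_cohort(mms, cohort),
                                 outcomes = c(A = 2, B = 1, C = 2)),
               "no outcome label.*D")
})

test_that("diagnostic metrics reproduce the count-derived study values", {
  mms_rep <- diagnostic_metrics(contingency_2x2(38, 19, 2, 162))
  expect_equal(report_metric(mms_rep, "specificity"), 162 / 181 * 100)
  expect_equal(round(report_metric(mms_rep, "specificity"), 2), 89.50)
  expect_equal(round(report_metric(mms_rep, "accuracy"), 2), 90.50)
  expect_equal(round(report_metric(mms_rep, "sensitivity"), 2), 95.00)

  meows_rep <- diagnostic_metrics(contingency_2x2(24, 27, 12, 158))
  expect_equal(round(report_metric(meows_rep, "npv"), 2), 92.94)

  perfect <- diagnostic_metrics(contingency_2x2(5, 0, 0, 7))
  expect_true(all(perfect$metrics$estimate == 100))
})

test_that("accuracy is the prevalence-weighted mean of sensitivity and specificity", {
  set.seed(5)
  for (i in 1:50) {
    tab <- random_contingency()
    m <- diagnostic_metrics(tab)$metrics
    est <- stats::setNames(m$estimate, m$metric)
    if (anyNA(est[c("sensitivity", "specificity")])) next
    prev <- (tab$tp + tab$fn) / (tab$tp + tab$fp + tab$fn + tab$tn)
    expect_equal(est[["accuracy"]],
                 prev * est[["sensitivity"]] + (1 - prev) * est[["specificity"]])
  }
})

test_that("point estimates are invariant under scaling all four cells", {
  set.seed(6)
  for (i in 1:20) {
    tab <- random_contingency()
    k <- sample(2:9, 1)
    scaled <- contingency_2x2(tab$tp * k, tab$fp * k, tab$fn * k, tab$tn * k)
    m1 <- diagnostic_metrics(tab)$metrics
    m2 <- diagnostic_metrics(scaled)$metrics
    expect_equal(m1$estimate, m2$estimate)
    # intervals shrink (or stay equal at the 0/100 boundary)
    ok <- is.na(m1$estimate) |
      (m2$upper - m2$lower) <= (m1$upper - m1$lower) + 1e-12
    expect_true(all(ok))
  }
})

test_that("zero-denominator metrics are undefined, not errors", {
  rep <- diagnostic_metrics(contingency_2x2(0, 0, 0, 10))
  m <- stats::setNames(rep$metrics$estimate, rep$metrics$metric)
  expect_true(is.na(m[["sensitivity"]]))
  expect_true(is.na(m[["ppv"]]))
  expect_equal(m[["specificity"]], 100)
  expect_equal(m[["accuracy"]], 100)
  expect_error(contingency_2x2(0, 0, 0, 0), "empty")
  expect_error(contingency_2x2(-1, 0, 0, 5), "non-negative")
})

test_that("Wilson intervals lie in [0,100], contain the estimate, and match prop.test", {
  set.seed(7)
  for (i in 1:50) {
    n <- sample(1:500, 1)
    x <- sample(0:n, 1)
    ci <- wilson_ci(x, n)
    expect_true(ci[["lower"]] >= 0 && ci[["upper"]] <= 1)
    expect_true(ci[["lower"]] <= x / n + 1e-12 &&
                ci[["upper"]] >= x / n - 1e-12)
    pt <- stats::prop.test(x, n, correct = FALSE)
    expect_equal(unname(ci), as.numeric(pt$conf.int), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("chi-square matches the textbook formula on random tables", {
  set.seed(8)
  for (i in 1:200) {
    nr <- sample(2:4, 1); nc <- sample(2:4, 1)
    m <- matrix(rpois(nr * nc, lambda = 8) + 1L, nr, nc)
    res <- chi_square_test(m)
    expect_equal(res$statistic, oracle_chisq(m), tolerance = 1e-10)
    expect_equal(res$df, (nr - 1) * (nc - 1))
    expect_equal(res$p_value,
                 stats::pchisq(res$statistic, res$df, lower.tail = FALSE))
  }
})

test_that("chi-square handles identical rows, corrections and degenerate margins", {
  flat <- matrix(c(10, 20, 10, 20), 2, 2)
  expect_equal(chi_square_test(flat)$statistic, 0)

  # Yates correction shrinks the 2x2 statistic
  m <- matrix(c(12, 5, 7, 14), 2, 2)
  expect_lt(chi_square_test(m, correct = TRUE)$statistic,
            chi_square_test(m)$statistic)

  sparse <- matrix(c(2, 1, 50, 60), 2, 2)
  expect_true(chi_square_test(sparse)$small_cells)
  expect_error(chi_square_test(matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE)),
               "zero marginal")
  expect_error(rxc_table(matrix(1:3, 3, 1)), "at least 2x2")
})

test_that("compare_charts reports deltas and degenerates to zero on self-comparison", {
  mms <- mms_chart()
  cohort <- list(
    make_record("A", overrides = list(`4` = list(rbs = 250)), outcome = 2L),
    make_record("B", overrides = list(`4` = list(hb = 5)), outcome = 1L),
    make_record("C", outcome = 2L),
    make_record("D", outcome = 1L),
    make_record("E", overrides = list(`4` = list(systolic_bp = 170)),
                outcome = 2L))
  self <- compare_charts(cohort, mms, mms)
  expect_true(all(self$deltas$delta == 0, na.rm = TRUE))
  expect_true(all(self$parameter_deltas$difference == 0))

  cmp <- compare_charts(cohort, mms, meows_chart())
  # biochemical triggers are invisible to the comparator
  expect_gt(report_metric(cmp$report_a, "sensitivity"),
            report_metric(cmp$report_b, "sensitivity"))
  expect_true(all(cmp$parameter_deltas$parameter %in%
                    chart_parameters(meows_chart())))
})

test_that("strictly wider alert thresholds can only lower the trigger rate", {
  # comparator whose orange/red cuts sit strictly outside the originals
  set.seed(9)
  narrow <- mms_chart()
  cohort <- generate_cohort(cohort_config(n_patients = 80), narrow, seed = 99)
  wide <- chart_definition("wide", list(
    parameter_spec("hb", "continuous", "g/dL", c(0, 25), list(
      zone_band("green", list(interval(9, Inf))),
      zone_band("orange", list(interval(4, 9, upper_closed = FALSE))),
      zone_band("red", list(interval(-Inf, 4, upper_closed = FALSE))))),
    parameter_spec("rbs", "continuous", "mg/dL", c(0, 2000), list(
      zone_band("green", list(interval(-Inf, 300, upper_closed = FALSE))),
      zone_band("red", list(interval(300, Inf, lower_closed = FALSE)))))))
  trig_narrow <- sum(vapply(
    evaluate_cohort(narrow, cohort), `[[`, logical(1), "triggered"))
  trig_wide <- sum(vapply(
    evaluate_cohort(wide, cohort, unknown_parameters = "ignore"),
    `[[`, logical(1), "triggered"))
  expect_lte(trig_wide, trig_narrow)
})
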