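# Scoring observation series and summarising cohorts.

mms <- mms_chart()

test_that("score_observation applies the trigger rule to supplied values only", {
  sc <- score_observation(mms, all_green_values())
  expect_false(sc$trigger)
  expect_identical(sc$n_red + sc$n_orange, 0L)
  expect_length(sc$unmeasured, 0)

  # one red fires the default rule
  sc_red <- score_observation(mms, list(rbs = 250))
  expect_true(sc_red$trigger)
  expect_identical(unname(sc_red$zones), "red")
  expect_setequal(sc_red$unmeasured, setdiff(chart_parameters(mms), "rbs"))

  # a single orange does not fire by default, but does at threshold 1
  sc_or <- score_observation(mms, list(heart_rate = 110))
  expect_false(sc_or$trigger)
  sensitive <- mms_chart(rule = trigger_rule(red = 1, orange = 1))
  expect_true(score_observation(sensitive, list(heart_rate = 110))$trigger)

  # two simultaneous oranges fire
  expect_true(score_observation(mms, list(heart_rate = 110,
                                          diastolic_bp = 95))$trigger)
})

test_that("unknown parameters error by default and are skippable", {
  expect_error(score_observation(mms, list(lactate = 2)), "does not monitor")
  sc <- score_observation(meows_chart(), list(hb = 5, heart_rate = 80),
                          unknown_parameters = "ignore")
  expect_identical(sc$skipped, "hb")
  expect_false(sc$trigger)
})

test_that("evaluate_patient finds the first triggering round and worst zones", {
  rec <- make_record(times = c(0, 4, 8, 12),
                     overrides = list(`8` = list(heart_rate = 110,
                                                 diastolic_bp = 95),
                                      `12` = list(spo2 = 90)))
  s <- evaluate_patient(mms, rec)
  expect_true(s$triggered)
  expect_identical(s$first_trigger_time_h, 8)
  expect_identical(s$per_parameter_worst[["heart_rate"]], "orange")
  expect_identical(s$per_parameter_worst[["spo2"]], "red")
  expect_identical(s$per_parameter_worst[["temperature"]], "green")

  # all-green record never triggers
  s0 <- evaluate_patient(mms, make_record())
  expect_false(s0$triggered)
  expect_true(is.na(s0$first_trigger_time_h))

  # a single transient haemoglobin dip drives the worst zone to red
  s_hb <- evaluate_patient(mms, make_record(
    overrides = list(`4` = list(hb = 5.8))))
  expect_identical(s_hb$per_parameter_worst[["hb"]], "red")
  expect_true(s_hb$triggered)
})

test_that("scoring errors carry patient and time context", {
  rec <- make_record(overrides = list(`4` = list(heart_rate = -5)))
  expect_error(evaluate_patient(mms, rec), "patient T1, t = 4 h")
})

test_that("records reject unsorted rounds and duplicate measurements", {
  obs <- rbind(obs_df(8, all_green_values()), obs_df(4, all_green_values()))
  expect_error(patient_record("P", obs), "strictly increasing")
  dup <- rbind(obs_df(0, list(hb = 12)), obs_df(0, list(hb = 11)))
  expect_error(patient_record("P", dup), "duplicate")
  none <- data.frame(time_h = numeric(0), parameter = character(0),
                     value = character(0))
  expect_error(patient_record("P", none), "no observations")
})

test_that("an added all-green round never changes trigger status or time", {
  set.seed(11)
  for (rep in 1:20) {
    t_der <- sample(c(0, 4, 8), 1)
    ov <- if (rep %% 2 == 0)
      stats::setNames(list(list(rbs = 250)), as.character(t_der)) else list()
    rec <- make_record(times = c(0, 4, 8), overrides = ov)
    aug <- make_record(times = c(0, 4, 8, 12), overrides = ov)
    s1 <- evaluate_patient(mms, rec)
    s2 <- evaluate_patient(mms, aug)
    expect_identical(s1$triggered, s2$triggered)
    expect_identical(s1$first_trigger_time_h, s2$first_trigger_time_h)
  }
})

test_that("escalating any single value never un-triggers a patient", {
  # replace one continuous value by a draw from a more severe band; the
  # patient-level flag must be monotone in severity
  set.seed(23)
  continuous <- Filter(
    function(p) chart_parameter(mms, p)$kind == "continuous",
    chart_parameters(mms))
  for (rep in 1:40) {
    ov <- list()
    if (rep %% 3 == 0) ov <- list(`4` = list(heart_rate = 110))
    if (rep %% 3 == 1) ov <- list(`4` = list(rbs = 250, hb = 5))
    rec <- make_record(overrides = ov)
    before <- evaluate_patient(mms, rec)$triggered

    p <- sample(continuous, 1)
    spec <- chart_parameter(mms, p)
    zones_avail <- vapply(spec$bands, `[[`, character(1), "zone")
    target <- if ("red" %in% zones_avail) "red" else "orange"
    v <- mmscreen:::sample_in_band(spec, target)
    esc <- make_record(overrides = utils::modifyList(
      ov, list(`8` = stats::setNames(list(v), p))))
    after <- evaluate_patient(mms, esc)$triggered
    expect_false(before && !after)
  }
})

test_that("check_schedule reports missing rounds, gaps and horizon breaches", {
  rec <- make_record(times = c(0, 4, 8), delivery_time_h = 2)
  rep1 <- check_schedule(rec, interval = 4, horizon_after_delivery = 24)
  expect_identical(rep1$expected_times, seq(0, 26, by = 4))
  expect_identical(rep1$missing_times, seq(12, 26, by = 4))
  expect_false(rep1$compliant)

  # zero horizon: only rounds up to delivery are expected
  rep0 <- check_schedule(rec, interval = 4, horizon_after_delivery = 0)
  expect_identical(rep0$expected_times, c(0))
  expect_length(rep0$missing_times, 0)
  expect_length(rep0$beyond_horizon, 2)

  irregular <- make_record(times = c(0, 9), delivery_time_h = 9)
  g <- check_schedule(irregular, interval = 4)
  expect_identical(nrow(g$gaps), 1L)
  expect_identical(g$gaps$gap_h, 9)

  full <- make_record(times = seq(0, 28, by = 4), delivery_time_h = 4)
  expect_true(check_schedule(full)$compliant)
})

test_that("cohort_summary counts, percentages and per-parameter tallies agree", {
  cohort <- list(
    make_record("A", overrides = list(`4` = list(hb = 9, proteinuria = "1+"))),
    make_record("B", overrides = list(`4` = list(hb = 5))),
    make_record("C"))
  cs <- cohort_summary(mms, cohort)
  expect_identical(cs$n, 3L)
  expect_identical(cs$n_triggered + cs$n_non_triggered, cs$n)
  expect_equal(cs$pct_triggered + cs$pct_non_triggered, 100)
  pt <- cs$parameter_table
  expect_identical(pt$abnormal[pt$parameter == "hb"], 2)
  expect_identical(pt$orange[pt$parameter == "hb"], 1)
  expect_identical(pt$red[pt$parameter == "hb"], 1)
  expect_identical(pt$abnormal[pt$parameter == "proteinuria"], 1)
  expect_true(all(pt$green + pt$orange + pt$red <= cs$n))

  single <- cohort_summary(mms, list(make_record("solo")))
  expect_identical(single$pct_triggered, 0)
  expect_identical(single$pct_non_triggered, 100)
})
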