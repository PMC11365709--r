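# Zone classification and chart definitions.

mms <- mms_chart()
meows <- meows_chart()

test_that("printed trigger thresholds classify per the canonicalization", {
  cl <- function(p, v) classify_value(chart_parameter(mms, p), v)

  # green bands own both printed endpoints
  expect_identical(cl("temperature", 36), "green")
  expect_identical(cl("temperature", 38), "green")
  expect_identical(cl("spo2", 95), "green")
  expect_identical(cl("heart_rate", 50), "green")
  expect_identical(cl("heart_rate", 100), "green")
  expect_identical(cl("respiratory_rate", 10), "green")
  expect_identical(cl("respiratory_rate", 20), "green")
  expect_identical(cl("systolic_bp", 100), "green")
  expect_identical(cl("systolic_bp", 140), "green")
  expect_identical(cl("hb", 11), "green")
  expect_identical(cl("wbc", 4.5), "green")
  expect_identical(cl("wbc", 11.0), "green")
  expect_identical(cl("platelets", 150), "green")
  expect_identical(cl("platelets", 400), "green")
  expect_identical(cl("sgpt", 56), "green")
  expect_identical(cl("bilirubin", 1.2), "green")
  expect_identical(cl("urea", 43), "green")
  expect_identical(cl("creatinine", 1.2), "green")

  # orange bands start at their printed bounds
  expect_identical(cl("temperature", 35), "orange")
  expect_identical(cl("heart_rate", 120), "orange")
  expect_identical(cl("heart_rate", 40), "orange")
  expect_identical(cl("respiratory_rate", 21), "orange")
  expect_identical(cl("respiratory_rate", 30), "orange")
  expect_identical(cl("systolic_bp", 90), "orange")
  expect_identical(cl("systolic_bp", 160), "orange")
  expect_identical(cl("diastolic_bp", 90), "orange")
  expect_identical(cl("diastolic_bp", 100), "orange")
  expect_identical(cl("hb", 6), "orange")
  expect_identical(cl("wbc", 3.5), "orange")
  expect_identical(cl("platelets", 20), "orange")

  # the blood-sugar boundary sits in a printed gap; severe side wins
  expect_identical(cl("rbs", 200), "red")
})

test_that("classification matches worked examples off the boundaries", {
  cl <- function(p, v) classify_value(chart_parameter(mms, p), v)
  expect_identical(cl("temperature", 37.0), "green")
  expect_identical(cl("heart_rate", 110), "orange")
  expect_identical(cl("heart_rate", 45), "orange")
  expect_identical(cl("systolic_bp", 170), "red")
  expect_identical(cl("respiratory_rate", 20.5), "orange")  # printed gap
  expect_identical(cl("hb", 11.5), "green")
  expect_identical(cl("hb", 5.0), "red")
  expect_identical(cl("rbs", 250), "red")
  expect_identical(cl("proteinuria", "trace"), "green")
  expect_identical(cl("proteinuria", "2+"), "orange")
  expect_identical(cl("proteinuria", "3+"), "red")
  expect_identical(cl("neural_response", "responds_to_voice"), "orange")
  expect_identical(cl("neural_response", "unresponsive"), "red")
  expect_identical(cl("general_condition", "looks_unwell"), "orange")
  expect_identical(cl("liquor", "thick_meconium"), "red")
})

test_that("classification is total over every built-in parameter domain", {
  for (chart in list(mms, meows)) {
    for (p in chart_parameters(chart)) {
      spec <- chart_parameter(chart, p)
      values <- if (spec$kind == "categorical") spec$domain else
        seq(spec$domain[1], spec$domain[2], length.out = 400)
      zones <- vapply(values, function(v) classify_value(spec, v),
                      character(1))
      expect_true(all(zones %in% ZONES),
                  info = paste(chart$name, p))
    }
  }
})

test_that("one-sided laboratory parameters have monotone severity", {
  for (p in c("bilirubin", "sgpt", "urea", "creatinine", "rbs")) {
    spec <- chart_parameter(mms, p)
    grid <- seq(spec$domain[1], spec$domain[2], length.out = 300)
    sev <- zone_severity(vapply(grid, function(v) classify_value(spec, v),
                                character(1)))
    expect_true(all(diff(sev) >= 0), info = p)
  }
})

test_that("out-of-domain and unknown values raise informative errors", {
  expect_error(classify_value(chart_parameter(mms, "heart_rate"), -10),
               "heart_rate.*outside admissible domain")
  expect_error(classify_value(chart_parameter(mms, "heart_rate"), NaN),
               "finite")
  expect_error(classify_value(chart_parameter(mms, "proteinuria"), "5+"),
               "unknown category")
  expect_error(chart_parameter(mms, "lactate"), "no parameter")
})

test_that("a gap value errors under strict gap handling", {
  spec <- chart_parameter(mms, "respiratory_rate")
  expect_error(classify_value(spec, 20.5, gaps = "strict"), "gap")
  expect_identical(classify_value(spec, 20.5, gaps = "severe"), "orange")
})

test_that("built-in charts validate; both carry the expected parameters", {
  v <- validate_chart(mms)
  expect_true(attr(v, "ok"))
  expect_true(attr(validate_chart(meows), "ok"))

  expect_length(chart_parameters(mms), 18)
  expect_length(chart_parameters(meows), 9)
  biochem <- c("hb", "rbs", "wbc", "platelets", "sgpt", "bilirubin",
               "urea", "creatinine", "proteinuria")
  expect_true(all(biochem %in% chart_parameters(mms)))
  expect_length(intersect(biochem, chart_parameters(meows)), 0)
})

test_that("validate_chart reports overlaps, gaps and missing green bands", {
  overlapping <- chart_definition("bad", list(
    parameter_spec("x", "continuous", "u", c(0, 10), list(
      zone_band("green", list(interval(0, 6))),
      zone_band("red", list(interval(5, Inf)))))))
  v <- validate_chart(overlapping)
  expect_false(attr(v, "ok"))
  expect_match(v$message[v$parameter == "x"], "overlap")

  gappy <- chart_definition("gappy", list(
    parameter_spec("x", "continuous", "u", c(0, 10), list(
      zone_band("green", list(interval(0, 4))),
      zone_band("red", list(interval(6, 10)))))))
  expect_true(attr(validate_chart(gappy, gaps = "severe"), "ok"))
  strict <- validate_chart(gappy, gaps = "strict")
  expect_false(attr(strict, "ok"))
  expect_match(strict$message[1], "not covered")

  expect_error(
    parameter_spec("x", "continuous", "u", c(0, 10),
                   list(zone_band("red", list(interval(0, 10))))),
    "green band")
})

test_that("the optional upper white-cell red cut reshapes the bands", {
  spec_default <- chart_parameter(mms, "wbc")
  expect_identical(classify_value(spec_default, 30), "orange")
  spec_cut <- chart_parameter(mms_chart(wbc_red_upper = 25), "wbc")
  expect_identical(classify_value(spec_cut, 30), "red")
  expect_identical(classify_value(spec_cut, 20), "orange")
})

test_that("trigger rule thresholds are validated", {
  expect_error(trigger_rule(red = 0), ">= 1")
  expect_error(trigger_rule(orange = -1), ">= 1")
  r <- trigger_rule(red = 2, orange = 3)
  expect_identical(c(r$red, r$orange), c(2L, 3L))
})
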