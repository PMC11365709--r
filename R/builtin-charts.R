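# Built-in screening charts.
#
# Interval canonicalization of the printed MMS trigger thresholds:
#  - green bands are closed on both printed bounds ("36-38" -> [36, 38]);
#  - orange bands adjoin green half-open where the print marks "<" or ">"
#    ("35-<36" -> [35, 36); ">100-120" -> (100, 120]);
#  - red takes the open exterior (">38 or <35" -> (38, Inf) U (-Inf, 35)).
# Printed integer-style gaps (respiratory rate between 20 and 21; random
# blood sugar at exactly 200) are left as gaps and resolve to the severe
# adjacent band at classification time.

iv <- function(lower, upper, lc = TRUE, uc = TRUE) {
  interval(lower, upper, lower_closed = lc, upper_closed = uc)
}

# Category -> zone maps shared by both charts (AVPU-style consciousness,
# overall appearance, amniotic-fluid colour).
neural_response_spec <- function() {
  parameter_spec(
    "neural_response", "categorical", unit = "AVPU",
    domain = c("alert", "responds_to_voice", "responds_to_pain",
               "unresponsive"),
    bands = list(
      zone_band("green", categories = "alert"),
      zone_band("orange", categories = "responds_to_voice"),
      zone_band("red", categories = c("responds_to_pain", "unresponsive"))))
}

general_condition_spec <- function() {
  parameter_spec(
    "general_condition", "categorical", unit = "appearance",
    domain = c("looks_well", "looks_unwell"),
    bands = list(
      zone_band("green", categories = "looks_well"),
      zone_band("orange", categories = "looks_unwell")))
}

liquor_spec <- function() {
  parameter_spec(
    "liquor", "categorical", unit = "colour",
    domain = c("clear", "meconium_stained", "thick_meconium",
               "blood_stained"),
    bands = list(
      zone_band("green", categories = "clear"),
      zone_band("orange", categories = "meconium_stained"),
      zone_band("red", categories = c("thick_meconium", "blood_stained"))))
}

#' Built-in maternal morbidity screening (MMS) chart
#'
#' The 18-parameter peripartum screening chart combining physiological vital
#' signs with biochemical laboratory parameters (haemoglobin, white cells,
#' platelets, liver enzymes, renal markers, random blood sugar, urine
#' protein). Zone thresholds follow the published trigger-threshold table
#' under the canonicalization documented in the package vignette: green
#' bands own their printed endpoints, orange bands adjoin half-open at
#' printed strict inequalities, red takes the open exterior, and printed
#' gaps (respiratory rate between 20 and 21; random blood sugar at exactly
#' 200) classify to the severe adjacent band.
#'
#' One-sided laboratory parameters (SGPT, bilirubin, urea, creatinine,
#' random blood sugar) alert only on elevation; values below the lower end
#' of the printed reference range remain green.
#'
#' @param rule The [trigger_rule()]; default fires on one red or two
#'   simultaneous orange parameters.
#' @param wbc_red_upper Optional upper white-cell red cut (10^9/L). The
#'   printed chart gives no interpretable upper red threshold ("irrespective"),
#'   so the default is none: high counts classify orange.
#' @return An `mms_chart` with 18 parameters.
#' @examples
#' chart <- mms_chart()
#' chart_parameters(chart)
#' classify_value(chart_parameter(chart, "hb"), 5)  # "red"
#' @export
mms_chart <- function(rule = trigger_rule(), wbc_red_upper = NULL) {
  wbc_orange <- list(iv(3.5, 4.5, uc = FALSE))
  wbc_red <- list(iv(-Inf, 3.5, uc = FALSE))
  if (is.null(wbc_red_upper)) {
    wbc_orange <- c(wbc_orange, list(iv(11, Inf, lc = FALSE)))
  } else {
    stopifnot(is.numeric(wbc_red_upper), wbc_red_upper > 11)
    wbc_orange <- c(wbc_orange, list(iv(11, wbc_red_upper, lc = FALSE)))
    wbc_red <- c(wbc_red, list(iv(wbc_red_upper, Inf, lc = FALSE)))
  }

  chart_definition("MMS", rule = rule, parameters = list(
    parameter_spec("temperature", "continuous", "°C", c(25, 45), list(
      zone_band("green", list(iv(36, 38))),
      zone_band("orange", list(iv(35, 36, uc = FALSE))),
      zone_band("red", list(iv(-Inf, 35, uc = FALSE), iv(38, Inf, lc = FALSE))))),
    parameter_spec("spo2", "continuous", "%", c(0, 100), list(
      zone_band("green", list(iv(95, 100))),
      zone_band("red", list(iv(-Inf, 95, uc = FALSE))))),
    parameter_spec("heart_rate", "continuous", "beats/min", c(0, 300), list(
      zone_band("green", list(iv(50, 100))),
      zone_band("orange", list(iv(100, 120, lc = FALSE),
                               iv(40, 50, uc = FALSE))),
      zone_band("red", list(iv(-Inf, 40, uc = FALSE),
                            iv(120, Inf, lc = FALSE))))),
    parameter_spec("respiratory_rate", "continuous", "breaths/min", c(0, 120),
      list(
        zone_band("green", list(iv(10, 20))),
        zone_band("orange", list(iv(21, 30))),
        zone_band("red", list(iv(-Inf, 10, uc = FALSE),
                              iv(30, Inf, lc = FALSE))))),
    parameter_spec("systolic_bp", "continuous", "mmHg", c(0, 350), list(
      zone_band("green", list(iv(100, 140))),
      zone_band("orange", list(iv(90, 100, uc = FALSE),
                               iv(140, 160, lc = FALSE))),
      zone_band("red", list(iv(-Inf, 90, uc = FALSE),
                            iv(160, Inf, lc = FALSE))))),
    parameter_spec("diastolic_bp", "continuous", "mmHg", c(0, 250), list(
      zone_band("green", list(iv(-Inf, 90, uc = FALSE))),
      zone_band("orange", list(iv(90, 100))),
      zone_band("red", list(iv(100, Inf, lc = FALSE))))),
    parameter_spec("proteinuria", "categorical", "dipstick",
      domain = c("nil", "trace", "1+", "2+", "3+", "4+"),
      bands = list(
        zone_band("green", categories = c("nil", "trace")),
        zone_band("orange", categories = c("1+", "2+")),
        zone_band("red", categories = c("3+", "4+")))),
    liquor_spec(),
    neural_response_spec(),
    general_condition_spec(),
    parameter_spec("hb", "continuous", "g/dL", c(0, 25), list(
      zone_band("green", list(iv(11, Inf))),
      zone_band("orange", list(iv(6, 11, uc = FALSE))),
      zone_band("red", list(iv(-Inf, 6, uc = FALSE))))),
    parameter_spec("wbc", "continuous", "10^9/L", c(0, 100), list(
      zone_band("green", list(iv(4.5, 11))),
      zone_band("orange", wbc_orange),
      zone_band("red", wbc_red))),
    parameter_spec("platelets", "continuous", "10^9/L", c(0, 2000), list(
      zone_band("green", list(iv(150, 400))),
      zone_band("orange", list(iv(20, 150, uc = FALSE),
                               iv(400, Inf, lc = FALSE))),
      zone_band("red", list(iv(-Inf, 20, uc = FALSE))))),
    parameter_spec("sgpt", "continuous", "IU/L", c(0, 10000), list(
      zone_band("green", list(iv(-Inf, 56))),
      zone_band("red", list(iv(56, Inf, lc = FALSE))))),
    parameter_spec("bilirubin", "continuous", "mg/dL", c(0, 75), list(
      zone_band("green", list(iv(-Inf, 1.2))),
      zone_band("red", list(iv(1.2, Inf, lc = FALSE))))),
    parameter_spec("urea", "continuous", "mg/dL", c(0, 500), list(
      zone_band("green", list(iv(-Inf, 43))),
      zone_band("red", list(iv(43, Inf, lc = FALSE))))),
    parameter_spec("creatinine", "continuous", "mg/dL", c(0, 50), list(
      zone_band("green", list(iv(-Inf, 1.2))),
      zone_band("red", list(iv(1.2, Inf, lc = FALSE))))),
    parameter_spec("rbs", "continuous", "mg/dL", c(0, 2000), list(
      zone_band("green", list(iv(-Inf, 200, uc = FALSE))),
      zone_band("red", list(iv(200, Inf, lc = FALSE)))))
  ))
}

#' Built-in MEOWS-style comparator chart
#'
#' A modified early obstetric warning system comparator restricted to the
#' physiological parameters monitored in both study arms: temperature,
#' oxygen saturation, heart rate, respiratory rate, systolic and diastolic
#' blood pressure, neural responsiveness, general condition and liquor
#' colour. It carries no biochemical parameters.
#'
#' Threshold values are shipped as editable CEMACH-convention defaults (for
#' example, temperature of 38 °C and above is a red alert, and systolic
#' pressure alerts from 150 mmHg); they are configuration, not values taken
#' from any validation study, and can be overridden by loading a chart JSON
#' file with [read_chart()].
#'
#' @param rule The [trigger_rule()]; default fires on one red or two
#'   simultaneous orange parameters.
#' @return An `mms_chart` with 9 parameters.
#' @export
meows_chart <- function(rule = trigger_rule()) {
  chart_definition("MEOWS", rule = rule, parameters = list(
    parameter_spec("temperature", "continuous", "°C", c(25, 45), list(
      zone_band("green", list(iv(36, 37.4))),
      zone_band("orange", list(iv(35, 36, uc = FALSE),
                               iv(37.4, 38, lc = FALSE, uc = FALSE))),
      zone_band("red", list(iv(-Inf, 35, uc = FALSE), iv(38, Inf))))),
    parameter_spec("spo2", "continuous", "%", c(0, 100), list(
      zone_band("green", list(iv(95, 100))),
      zone_band("red", list(iv(-Inf, 95, uc = FALSE))))),
    parameter_spec("heart_rate", "continuous", "beats/min", c(0, 300), list(
      zone_band("green", list(iv(50, 100))),
      zone_band("orange", list(iv(100, 120, lc = FALSE),
                               iv(40, 50, uc = FALSE))),
      zone_band("red", list(iv(-Inf, 40, uc = FALSE),
                            iv(120, Inf, lc = FALSE))))),
    parameter_spec("respiratory_rate", "continuous", "breaths/min", c(0, 120),
      list(
        zone_band("green", list(iv(10, 20))),
        zone_band("orange", list(iv(21, 30))),
        zone_band("red", list(iv(-Inf, 10, uc = FALSE),
                              iv(30, Inf, lc = FALSE))))),
    parameter_spec("systolic_bp", "continuous", "mmHg", c(0, 350), list(
      zone_band("green", list(iv(100, 150, uc = FALSE))),
      zone_band("orange", list(iv(90, 100, uc = FALSE), iv(150, 160))),
      zone_band("red", list(iv(-Inf, 90, uc = FALSE),
                            iv(160, Inf, lc = FALSE))))),
    parameter_spec("diastolic_bp", "continuous", "mmHg", c(0, 250), list(
      zone_band("green", list(iv(-Inf, 90, uc = FALSE))),
      zone_band("orange", list(iv(90, 100))),
      zone_band("red", list(iv(100, Inf, lc = FALSE))))),
    neural_response_spec(),
    general_condition_spec(),
    liquor_spec()
  ))
}

#' Resolve a built-in chart by name
#'
#' @param name `"MMS"` or `"MEOWS"` (case-insensitive).
#' @return An `mms_chart`.
#' @export
builtin_chart <- function(name) {
  switch(toupper(name),
         MMS = mms_chart(),
         MEOWS = meows_chart(),
         stop("unknown built-in chart '", name,
              "'; available: MMS, MEOWS"))
}
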