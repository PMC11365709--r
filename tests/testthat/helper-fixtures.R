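# Shared in-code fixtures for the test suite.

# an observation round with every MMS parameter in its normal band
all_green_values <- function() {
  list(temperature = 37, spo2 = 98, heart_rate = 80, respiratory_rate = 16,
       systolic_bp = 120, diastolic_bp = 75, proteinuria = "nil",
       liquor = "clear", neural_response = "alert",
       general_condition = "looks_well", hb = 12, wbc = 7, platelets = 250,
       sgpt = 25, bilirubin = 0.8, urea = 30, creatinine = 0.9, rbs = 110)
}

obs_df <- function(time_h, values) {
  data.frame(time_h = time_h, parameter = names(values),
             value = vapply(values, as.character, character(1)),
             stringsAsFactors = FALSE)
}

# record with one all-green round per time; `overrides` is a named list of
# named value lists keyed by time
make_record <- function(id = "T1", times = c(0, 4, 8), overrides = list(),
                        outcome = 1L, delivery_time_h = 4,
                        delivery_mode = NA_character_) {
  rows <- lapply(times, function(t) {
    vals <- all_green_values()
    ov <- overrides[[as.character(t)]]
    if (!is.null(ov)) vals[names(ov)] <- ov
    obs_df(t, vals)
  })
  patient_record(id, do.call(rbind, rows), delivery_time_h = delivery_time_h,
                 outcome = outcome, delivery_mode = delivery_mode)
}

outcomes_of <- function(cohort) {
  stats::setNames(vapply(cohort, `[[`, integer(1), "outcome"),
                  vapply(cohort, `[[`, character(1), "patient_id"))
}

# textbook Pearson chi-square, independent of chi_square_test()
oracle_chisq <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - e)^2 / e)
}

random_contingency <- function() {
  contingency_2x2(sample(0:60, 1), sample(0:60, 1),
                  sample(0:60, 1), sample(1:60, 1))
}
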