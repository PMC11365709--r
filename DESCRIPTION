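Package: mmscreen
Title: Maternal Morbidity Screening Charts and Diagnostic Accuracy Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Rule-based track-and-trigger screening for peripartum morbidity.
    Represents early-warning charts (an 18-parameter maternal morbidity
    screening chart with physiological and biochemical trigger bands, and a
    configurable MEOWS-style vital-signs comparator) as data, classifies
    4-hourly observations into green/orange/red zones, dichotomises patients
    into triggered and non-triggered groups, and evaluates screening
    performance against morbidity outcomes via contingency tables,
    sensitivity/specificity/predictive values with Wilson score intervals,
    and Pearson chi-square tests. Includes a synthetic labour-ward cohort
    generator so every pipeline stage is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
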