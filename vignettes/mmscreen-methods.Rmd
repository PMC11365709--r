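---
title: "Methods: trigger-zone screening charts and their validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trigger-zone screening charts and their validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmscreen)
```

## The screening problem

Most severe maternal complications cluster in the peripartum window —
labour through the first 24 hours after delivery. Track-and-trigger
charts address this by classifying each routinely monitored parameter
into a colour zone (green = normal, orange = low-risk alert, red =
high-risk alert) at every observation round, and escalating care as soon
as a round crosses a trigger rule. The classical MEOWS-style charts use
vital signs only; the maternal morbidity screening (MMS) chart modelled
here extends them with biochemical parameters (haemoglobin, white cells,
platelets, SGPT, bilirubin, urea, creatinine, random blood sugar, urine
protein), on the rationale that multisystem involvement — anaemia,
preeclampsia, gestational diabetes — often shows in laboratory work
before it shows at the bedside.

`mmscreen` treats a chart as *data*: an ordered set of parameter
specifications, each with zone bands over an admissible domain, plus a
trigger aggregation rule. Everything downstream — patient scoring, cohort
tallies, diagnostic accuracy — is generic over the chart.

## Interval canonicalization

Printed threshold tables are ambiguous about boundaries ("36–38",
"35–<36", ">38 or <35"). The built-in charts encode them under one
explicit convention:

* **Green bands own both printed endpoints**: "36–38 °C" becomes
  [36, 38]. A temperature of exactly 38.0 °C is therefore *normal* on the
  MMS chart.
* **Orange bands adjoin half-open at printed strict inequalities**:
  "35–<36" becomes [35, 36); ">100–120" becomes (100, 120].
* **Red takes the open exterior**: ">38 or <35" becomes
  (38, ∞) ∪ (−∞, 35).

Every interval carries explicit bound-inclusivity flags; nothing is
string-parsed at classification time. The chart JSON format
(`write_chart()` / `read_chart()`) preserves these flags and round-trips
charts losslessly.

Some printed rows need interpretation beyond the boundary convention;
these readings are deliberate design choices, encoded once:

* **One-sided laboratory parameters** (SGPT "7–56, red >56"; bilirubin;
  urea; creatinine; random blood sugar): only elevation is flagged.
  Values below the lower end of the printed reference range stay green —
  no low-side alert exists anywhere in the source material for these
  rows.
* **Haemoglobin**: green is ≥11 g/dL (the printed "11–12 g/dL" is a
  reference range, not an upper alert); orange [6, 11); red <6.
* **White cells**: orange is *outside* the 4.5–11.0 normal range (i.e.
  [3.5, 4.5) or >11.0); red <3.5. The printed upper red cell is not
  interpretable ("irrespective"), so the default chart has no upper red
  cut; `mms_chart(wbc_red_upper = )` adds one.
* **Platelets**: orange outside [150, 400] (down to 20, or above 400);
  the printed 10–20 red span is folded into a single conservative red cut
  below 20.
* **Proteinuria** is an ordered dipstick scale
  {nil, trace, 1+, 2+, 3+, 4+} encoded as categories (green through
  trace, orange 1+–2+, red above 2+), never as numbers.
* **Consciousness** follows AVPU: alert → green, responds to voice →
  orange, responds to pain or unresponsive → red. **General condition**
  has no red band (looks well / looks unwell only).
* **Liquor colour** is monitored alongside the numbered parameters but
  carries no printed thresholds; the shipped mapping (clear → green,
  meconium-stained → orange, thick meconium or blood-stained → red) is a
  package default and fully configurable through the chart JSON.

### Gap resolution

Two printed thresholds leave genuine gaps: respiratory rate between the
normal band ending at 20 and the orange band starting at 21, and random
blood sugar at exactly 200 mg/dL between "<200" and ">200". A value in
such a gap resolves to the **more severe adjacent band** (20.5
breaths/min → orange; 200 mg/dL → red). Screening instruments err
conservative: the cost of a false alert is a repeat observation, the cost
of a missed one is an undetected deterioration. `classify_value(...,
gaps = "strict")` turns gaps into errors instead, and `validate_chart()`
reports them either way.

## The trigger rule and patient-level status

The source material dichotomises patients into trigger and non-trigger
groups but never states the aggregation rule. The package default is the
CEMACH/MEOWS convention — **≥1 red or ≥2 simultaneous orange parameters
in a single observation round** — with both counts configurable
(`trigger_rule()`). Simultaneity is within a round: two oranges four
hours apart do not fire.

A patient is *triggered* if any round of their series fires the rule;
`first_trigger_time_h` is the earliest such round. This
single-observation basis is the only reading consistent with
trigger-group membership over a monitored window; persistence-based rules
(alerts on consecutive rounds) are intentionally out of scope. Parameters
not measured in a round contribute nothing — there is no imputation, and
alert counts run over measured values only. Laboratory parameters need
not be re-measured 4-hourly; the per-parameter worst zone uses whatever
measurements exist.

Two monotonicity properties follow from this design and are enforced by
tests: adding an all-green round never changes a patient's status, and
replacing any single value by a more severe one never un-triggers a
patient.

## The MEOWS comparator

`meows_chart()` restricts to the nine physiological parameters monitored
in both study arms (temperature, oxygen saturation, heart rate,
respiratory rate, systolic and diastolic pressure, consciousness, general
condition, liquor). Its thresholds are shipped as *editable
CEMACH-convention defaults* — e.g. red from 38 °C and a systolic alert
from 150 mmHg — because the source material prints no MEOWS threshold
table. They are configuration, not validated values, and the package
never asserts them against published numbers.

## Diagnostic accuracy

With screen-positive = triggered and disease-positive = outcome
category 2 (obstetric morbidity during the stay), the 2×2 table gives
sensitivity TP/(TP+FN), specificity TN/(TN+FP), PPV TP/(TP+FP), NPV
TN/(TN+FN) and accuracy (TP+TN)/N, reported as percentages. Each
estimate carries a **Wilson score interval** (default 95%): the source
material prints no intervals, and Wilson behaves better than Wald at the
small counts involved (2/164, 38/40). Zero-denominator metrics are
reported as undefined (`NA`) rather than erroring, so degenerate cohorts
survive batch evaluation. Accuracy is checked in tests as the
prevalence-weighted mean of sensitivity and specificity.

Group comparisons use Pearson's chi-square without continuity correction
by default (`chi_square_test(x, correct = TRUE)` enables Yates); the
delivery-mode table's assisted column has expected counts near 1 and 3,
so the result carries a small-cell warning flag.

### Published values the package does not reproduce

Several printed summary statistics are arithmetically inconsistent with
their own cross-tabulated counts: printed MMS sensitivity 95.24% vs
38/40 = 95.00%, MMS PPV 70.24% vs 38/57 = 66.67%, MMS NPV 98.50% vs
162/164 = 98.78%, and the MEOWS sensitivity/specificity/accuracy trio
(70.51 / 86.81 / 83.71) vs 24/36 = 66.67, 158/185 = 85.41,
182/221 = 82.35. How those figures were obtained is not stated — possibly
a different denominator or subgroup. The package computes metrics from
counts and its tests assert only the count-consistent printed values
(specificity 89.50, accuracy 90.50, NPV 92.94, trigger rates, the
chi-square 16.65). Printed percentages are truncated rather than rounded
in places (23.07% for 51/221, 66.66% for 38/57); tests compare at the
printed precision.

## The worked study arms

The validation study enrolled 441 women in labour (gestation >28 weeks)
and monitored two separate 221-patient arms, one per chart — the two
outcome columns of its cross-tab imply 40 vs 36 morbid patients, so they
cannot be one cohort. `study_fixture_cohort()` therefore builds two
deterministic arms:

* the **MMS arm** scores to the exact published margins under
  `mms_chart()`: 57 triggered (38 morbid / 19 not), 164 non-triggered
  (2 / 162), and the delivery-mode split 35/20/2 vs 54/108/2;
* the **MEOWS arm** scores to 51 triggered (24 / 27) and 170
  non-triggered (12 / 158) under `meows_chart()`.

The published tables fix only those margins. Within the MMS arm the
joint MMS-by-MEOWS trigger structure is a construction choice, chosen to
exercise every cross-chart pathway: joint triggers are physiological reds
visible to both charts, MMS-only triggers are biochemical derangements
the comparator cannot see, and MEOWS-only triggers exploit the one
threshold the two charts disagree on (38.0 °C, normal on MMS, red on the
comparator). Any overlap between 0 and the margin minima would reproduce
the same published tables. The arms contain no random draws, so
regeneration is byte-identical.

## The synthetic cohort generator

`generate_cohort()` emulates the study conditions, not real physiology.
Its defaults *are* the study's: 221 patients, morbidity prevalence
40/221 ≈ 0.181, trigger sensitivity 0.95 and specificity 0.895 against
morbidity, 4-hourly observations from enrolment until 24 h after a
delivery time drawn uniformly in (0, 24] h, and derangement frequencies
proportional to the published per-parameter abnormal-zone tallies
(Hb 13 : proteinuria 15 : WBC 9 : SGPT 9 : creatinine 8 : RBS 7 :
urea 4 : platelets 3 : bilirubin 2). Under these targets the implied
trigger prevalence is 0.95·0.181 + 0.105·0.819 ≈ 0.258, matching the
published 25.79% trigger rate.

Generation is by construction: morbidity and intended trigger status are
drawn first, then values are sampled *inside* the zone bands that realise
that status — uniformly within a band's within-domain length, with open
bounds shrunk by a relative 10⁻⁶ margin so a draw can never land on a
boundary owned by the adjacent band. Triggered patients derange 1–3
parameters (probabilities 0.80/0.17/0.03, mean ≈ 1.2, consistent with
roughly 70 abnormalities across 57 triggered patients) in one randomly
chosen round, all-orange or red-led as the rule requires; non-triggered
patients stay green apart from an optional single sub-trigger orange
excursion (probability defaulting to 1 − specificity target), so
parameter-level specificity is not trivially perfect. Because generation
and scoring share the band definitions, scoring a generated cohort
recovers the intended status for 100% of patients — a round-trip identity
the tests assert exactly, which in turn justifies calibrating prevalence
on the generator's intent labels for large cohorts.

What the generator does **not** emulate: autocorrelated vital-sign
trajectories, treatment effects after triggering, missing rounds,
measurement error, or any joint distribution between parameters beyond
the derangement draw. Passing tests therefore demonstrate that the
scoring engine, the evaluation statistics and the generator are mutually
consistent under the study's marginal structure — not that the charts
would achieve these operating characteristics on real patients.

## Numerical choices and problem sizes

* Chart validation sweeps each continuous domain on a 501-point grid plus
  every band boundary; categorical domains are enumerated.
* Percentages are kept at full precision internally; printing rounds to
  two decimals.
* Observation values travel as strings in the long-format CSV (one
  column serves continuous and categorical parameters) and are coerced
  per the parameter's declared kind at classification time, with
  malformed values rejected by name, patient and time.
* The test suite exercises the worked 221-patient arms, cohorts of
  40–300 for property checks, and a 10,000-patient cohort for generator
  calibration (within 3 Monte-Carlo standard errors of the implied
  prevalence); these sizes give stable checks at interactive runtimes.
* `check_schedule()` matches expected to observed rounds with a 0.5 h
  tolerance; it is advisory and never blocks scoring.

## Known limitations

* The trigger rule is a per-round threshold count; weighted scores (NEWS
  -style aggregate points) are representable only as zone counts.
* No ROC analysis: charts emit categorical zones, not continuous risk
  scores.
* The MEOWS comparator's thresholds are conventions, not a re-derivation
  of the CEMACH source report.
* Outcome labels are binary (morbidity during stay yes/no); no
  time-to-event structure, although first-trigger times are recorded.
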