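# Synthetic labour-ward cohorts.
#
# The generator works by construction: it first draws each patient's
# morbidity status and intended trigger status from the configured
# conditional probabilities, then samples parameter values inside the zone
# bands that realise exactly that status. Scoring a generated cohort with
# the same chart therefore recovers the intended trigger status for every
# patient (a round-trip identity the test suite checks).

# Parameters re-measured every round; everything else is laboratory work
# measured at enrolment (and re-drawn at the derangement round).
PHYSIOLOGICAL_PARAMETERS <- c(
  "temperature", "spo2", "heart_rate", "respiratory_rate", "systolic_bp",
  "diastolic_bp", "neural_response", "general_condition", "liquor")

#' Configuration of the synthetic cohort generator
#'
#' Defaults emulate the validation study's labour-ward cohort: 221 patients
#' monitored 4-hourly until 24 h post-delivery, morbidity prevalence
#' 40/221, trigger sensitivity 0.95 and specificity 0.895 against
#' morbidity, and derangements distributed over the biochemical parameters
#' proportionally to the published abnormal-zone tallies.
#'
#' @param n_patients Cohort size.
#' @param morbidity_prevalence P(outcome category 2).
#' @param trigger_sensitivity_target P(trigger | morbid).
#' @param trigger_specificity_target P(no trigger | healthy).
#' @param per_parameter_derangement Named non-negative weights: probability
#'   (up to normalisation) that a triggering derangement involves each
#'   parameter. Names must be chart parameters with a red band.
#' @param derangement_multiplicity_probs Probabilities that a triggered
#'   patient deranges 1, 2 or 3 parameters simultaneously (mean ~1.2,
#'   matching roughly 70 abnormalities over 57 triggered patients).
#' @param orange_excursion_prob Probability that a non-triggered patient
#'   shows one sub-trigger orange excursion (so specificity of individual
#'   parameters is not trivially perfect). Default: 1 - specificity target.
#' @param observation_interval Monitoring interval, hours.
#' @param horizon_after_delivery Post-delivery monitoring horizon, hours.
#' @param seed Optional integer seed; [generate_cohort()] sets it.
#' @return An object of class `"cohort_config"`.
#' @export
cohort_config <- function(n_patients = 221L,
                          morbidity_prevalence = 40 / 221,
                          trigger_sensitivity_target = 0.95,
                          trigger_specificity_target = 0.895,
                          per_parameter_derangement = c(
                            hb = 13, proteinuria = 15, wbc = 9, sgpt = 9,
                            creatinine = 8, rbs = 7, urea = 4, platelets = 3,
                            bilirubin = 2),
                          derangement_multiplicity_probs = c(0.8, 0.17, 0.03),
                          orange_excursion_prob = NULL,
                          observation_interval = 4,
                          horizon_after_delivery = 24,
                          seed = NULL) {
  if (is.null(orange_excursion_prob)) {
    orange_excursion_prob <- 1 - trigger_specificity_target
  }
  probs <- c(morbidity_prevalence, trigger_sensitivity_target,
             trigger_specificity_target, orange_excursion_prob)
  stopifnot(n_patients >= 1L, all(probs >= 0), all(probs <= 1),
            observation_interval > 0, horizon_after_delivery >= 0,
            is.numeric(per_parameter_derangement),
            !is.null(names(per_parameter_derangement)),
            all(per_parameter_derangement >= 0),
            sum(per_parameter_derangement) > 0,
            length(derangement_multiplicity_probs) == 3L,
            all(derangement_multiplicity_probs >= 0),
            sum(derangement_multiplicity_probs) > 0)
  structure(list(
    n_patients = as.integer(n_patients),
    morbidity_prevalence = morbidity_prevalence,
    trigger_sensitivity_target = trigger_sensitivity_target,
    trigger_specificity_target = trigger_specificity_target,
    per_parameter_derangement = per_parameter_derangement,
    derangement_multiplicity_probs =
      derangement_multiplicity_probs / sum(derangement_multiplicity_probs),
    orange_excursion_prob = orange_excursion_prob,
    observation_interval = observation_interval,
    horizon_after_delivery = horizon_after_delivery,
    seed = seed), class = "cohort_config")
}

band_for_zone <- function(spec, zone) {
  for (b in spec$bands) if (b$zone == zone) return(b)
  NULL
}

has_zone <- function(spec, zone) !is.null(band_for_zone(spec, zone))

# Sampleable segments of one zone band, clamped to the parameter domain.
# Open bounds are shrunk by a small margin so a sampled value can never sit
# on a boundary owned by the adjacent band.
band_segments <- function(spec, zone) {
  b <- band_for_zone(spec, zone)
  if (is.null(b)) {
    stop("parameter '", spec$name, "' has no ", zone, " band")
  }
  segs <- lapply(b$intervals, function(ivl) {
    lo <- max(ivl$lower, spec$domain[1])
    hi <- min(ivl$upper, spec$domain[2])
    if (hi <= lo) return(NULL)
    eps <- (hi - lo) * 1e-6
    if (!ivl$lower_closed && lo == ivl$lower) lo <- lo + eps
    if (!ivl$upper_closed && hi == ivl$upper) hi <- hi - eps
    c(lo, hi)
  })
  segs <- segs[!vapply(segs, is.null, logical(1))]
  if (length(segs) == 0L) {
    stop("parameter '", spec$name, "': ", zone,
         " band empty within the domain")
  }
  do.call(rbind, segs)
}

# n uniform draws inside one zone band (uniform over the band's total
# within-domain length; categorical bands draw category labels uniformly).
sample_in_band_n <- function(spec, zone, n) {
  if (spec$kind == "categorical") {
    cats <- band_for_zone(spec, zone)
    if (is.null(cats)) stop("parameter '", spec$name, "' has no ", zone,
                            " band")
    return(cats$categories[sample.int(length(cats$categories), n,
                                      replace = TRUE)])
  }
  segs <- band_segments(spec, zone)
  len <- segs[, 2] - segs[, 1]
  idx <- if (nrow(segs) == 1L) rep(1L, n) else
    sample.int(nrow(segs), n, replace = TRUE, prob = len)
  stats::runif(n, segs[idx, 1], segs[idx, 2])
}

sample_in_band <- function(spec, zone) sample_in_band_n(spec, zone, 1L)

# Zone assignment for a triggering derangement: which of the selected
# parameters go red vs orange so the chart's rule is guaranteed to fire.
derangement_zones <- function(chart, params) {
  rule <- chart$trigger_rule
  specs <- lapply(params, chart_parameter, chart = chart)
  all_orange_ok <- length(params) >= rule$orange &&
    all(vapply(specs, has_zone, logical(1), zone = "orange"))
  if (all_orange_ok && stats::runif(1) < 0.5) {
    return(stats::setNames(rep("orange", length(params)), params))
  }
  zones <- stats::setNames(rep("red", length(params)), params)
  if (length(params) > rule$red) {
    extra <- seq.int(rule$red + 1L, length(params))
    for (i in extra) {
      if (has_zone(specs[[i]], "orange") && stats::runif(1) < 0.6) {
        zones[i] <- "orange"
      }
    }
    # never let the mix drop below a firing combination
    if (sum(zones == "red") < rule$red) {
      zones[seq_len(rule$red)] <- "red"
    }
  }
  zones
}

#' Generate a synthetic labour-ward cohort
#'
#' Draws each patient's morbidity status and intended trigger status from
#' the configured targets, then constructs a 4-hourly peripartum
#' observation series realising that status under `chart`: triggered
#' patients carry one observation round whose deranged parameter values
#' fire the chart's trigger rule, non-triggered patients stay sub-threshold
#' throughout (all green, or at most one orange excursion). Values are
#' drawn uniformly within the target zone band.
#'
#' @param config A [cohort_config()].
#' @param chart The chart the cohort is constructed against (default
#'   [mms_chart()]); it must pass [validate_chart()].
#' @param seed Integer seed (overrides `config$seed`). The output is fully
#'   reproducible from the seed.
#' @return A list of [patient_record()] objects, with attribute `"intent"`:
#'   a data.frame (`patient_id`, `morbid`, `intended_trigger`,
#'   `deranged_parameters`) recording the construction, and attribute
#'   `"seed"`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 20), seed = 1)
#' summaries <- evaluate_cohort(mms_chart(), cohort)
#' @export
generate_cohort <- function(config = cohort_config(), chart = mms_chart(),
                            seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"), inherits(chart, "mms_chart"))
  val <- validate_chart(chart)
  if (!attr(val, "ok")) stop("chart '", chart$name, "' fails validation")
  if (!is.null(seed)) set.seed(as.integer(seed))

  weights <- config$per_parameter_derangement
  unknown <- setdiff(names(weights), chart_parameters(chart))
  if (length(unknown)) {
    stop("derangement parameters not on the chart: ",
         paste(unknown, collapse = ", "))
  }
  redable <- vapply(names(weights), function(p)
    has_zone(chart_parameter(chart, p), "red"), logical(1))
  orangeable <- vapply(names(weights), function(p)
    has_zone(chart_parameter(chart, p), "orange"), logical(1))
  if (!any(redable[weights > 0])) {
    stop("unsatisfiable config: no weighted derangement parameter has a ",
         "red band on chart '", chart$name, "'")
  }
  rule <- chart$trigger_rule
  excursion_possible <- rule$orange >= 2L && any(orangeable)

  phys <- intersect(chart_parameters(chart), PHYSIOLOGICAL_PARAMETERS)
  labs <- setdiff(chart_parameters(chart), phys)

  n <- config$n_patients
  ids <- sprintf("P%05d", seq_len(n))
  morbid <- stats::runif(n) < config$morbidity_prevalence
  intended <- ifelse(morbid,
                     stats::runif(n) < config$trigger_sensitivity_target,
                     stats::runif(n) >= config$trigger_specificity_target)

  records <- vector("list", n)
  deranged_desc <- character(n)
  for (i in seq_len(n)) {
    delivery <- stats::runif(1, 0, 24)
    times <- seq(0, delivery + config$horizon_after_delivery,
                 by = config$observation_interval)
    n_t <- length(times)

    # green baseline: vitals every round, laboratory work at enrolment
    phys_vals <- unlist(lapply(phys, function(p)
      as.character(sample_in_band_n(chart_parameter(chart, p), "green", n_t))))
    lab_vals <- vapply(labs, function(p)
      as.character(sample_in_band(chart_parameter(chart, p), "green")),
      character(1))
    obs <- data.frame(
      time_h = c(rep(times, times = length(phys)), rep(0, length(labs))),
      parameter = c(rep(phys, each = n_t), labs),
      value = c(phys_vals, lab_vals),
      stringsAsFactors = FALSE)

    if (intended[i]) {
      k <- sample.int(3L, 1L, prob = config$derangement_multiplicity_probs)
      k <- max(k, rule$red)
      pool <- names(weights)[weights > 0 & redable]
      k <- min(k, length(pool))
      sel <- if (length(pool) == 1L) pool else
        sample(pool, k, prob = weights[pool])
      zones <- derangement_zones(chart, sel)
      t_der <- times[sample.int(length(times), 1L)]
      for (p in names(zones)) {
        v <- as.character(sample_in_band(chart_parameter(chart, p), zones[p]))
        hit <- obs$time_h == t_der & obs$parameter == p
        if (any(hit)) obs$value[hit] <- v
        else obs <- rbind(obs, data.frame(time_h = t_der, parameter = p,
                                          value = v, stringsAsFactors = FALSE))
      }
      deranged_desc[i] <- paste(names(zones), unname(zones), sep = ":",
                                collapse = ";")
    } else if (excursion_possible &&
               stats::runif(1) < config$orange_excursion_prob) {
      pool <- names(weights)[weights > 0 & orangeable]
      if (length(pool)) {
        p <- if (length(pool) == 1L) pool else
          sample(pool, 1L, prob = weights[pool])
        t_exc <- times[sample.int(length(times), 1L)]
        v <- as.character(sample_in_band(chart_parameter(chart, p), "orange"))
        hit <- obs$time_h == t_exc & obs$parameter == p
        if (any(hit)) obs$value[hit] <- v
        else obs <- rbind(obs, data.frame(time_h = t_exc, parameter = p,
                                          value = v, stringsAsFactors = FALSE))
        deranged_desc[i] <- paste0(p, ":orange(sub-trigger)")
      }
    }

    obs <- obs[order(obs$time_h), , drop = FALSE]
    records[[i]] <- patient_record(
      ids[i], obs, delivery_time_h = delivery,
      outcome = if (morbid[i]) 2L else 1L,
      delivery_mode = sample(c("normal", "lscs", "assisted"), 1L,
                             prob = c(0.5, 0.45, 0.05)))
  }

  structure(records,
            intent = data.frame(patient_id = ids, morbid = morbid,
                                intended_trigger = intended,
                                deranged_parameters = deranged_desc,
                                stringsAsFactors = FALSE),
            seed = seed)
}
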