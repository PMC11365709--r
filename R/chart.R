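#' @title Zone severity levels
#' @description Screening zones in increasing severity: `"green"` (normal),
#'   `"orange"` (low-risk alert), `"red"` (high-risk alert).
#' @format A character vector of length 3, ordered from least to most severe.
#' @export
ZONES <- c("green", "orange", "red")

#' Numeric severity of a zone
#'
#' Maps zone labels to integer severity under the total order
#' green < orange < red.
#'
#' @param zone Character vector of zone labels.
#' @return Integer vector: 1 (green), 2 (orange), 3 (red).
#' @export
zone_severity <- function(zone) {
  lev <- match(zone, ZONES)
  if (anyNA(lev)) {
    stop("unknown zone label: ", paste(unique(zone[is.na(lev)]), collapse = ", "))
  }
  lev
}

#' Worst (most severe) zone among labels
#'
#' @param zones Character vector of zone labels; `NA`s are dropped.
#' @return A single zone label, or `NA_character_` if no zones supplied.
#' @export
worst_zone <- function(zones) {
  zones <- zones[!is.na(zones)]
  if (length(zones) == 0L) return(NA_character_)
  ZONES[max(zone_severity(zones))]
}

#' Numeric interval with explicit bound inclusivity
#'
#' Building block for continuous zone bands. Bounds may be infinite
#' (`-Inf` / `Inf`); infinite bounds are always treated as open.
#'
#' @param lower,upper Numeric bounds, `lower < upper` when both finite.
#' @param lower_closed,upper_closed Whether the bound itself belongs to the
#'   interval.
#' @return An object of class `"mms_interval"`.
#' @export
interval <- function(lower, upper, lower_closed = TRUE, upper_closed = TRUE) {
  stopifnot(is.numeric(lower), is.numeric(upper), length(lower) == 1L,
            length(upper) == 1L)
  if (is.finite(lower) && is.finite(upper) && lower >= upper) {
    stop("interval requires lower < upper; got [", lower, ", ", upper, "]")
  }
  if (!is.finite(lower)) lower_closed <- FALSE
  if (!is.finite(upper)) upper_closed <- FALSE
  structure(
    list(lower = lower, upper = upper,
         lower_closed = isTRUE(lower_closed),
         upper_closed = isTRUE(upper_closed)),
    class = "mms_interval"
  )
}

in_interval <- function(iv, x) {
  lo <- if (iv$lower_closed) x >= iv$lower else x > iv$lower
  hi <- if (iv$upper_closed) x <= iv$upper else x < iv$upper
  lo & hi
}

format_interval <- function(iv) {
  paste0(if (iv$lower_closed) "[" else "(", iv$lower, ", ", iv$upper,
         if (iv$upper_closed) "]" else ")")
}

#' Zone band of a screening parameter
#'
#' One severity band: the zone label plus either a set of numeric intervals
#' (continuous parameters; disjoint bands like heart-rate orange
#' "above 100 up to 120, or 40 up to below 50" use two intervals) or a set of
#' category labels (categorical/ordinal parameters).
#'
#' @param zone One of [ZONES].
#' @param intervals A list of [interval()] objects (continuous parameters).
#' @param categories Character vector of category labels (categorical
#'   parameters). Exactly one of `intervals`/`categories` must be given.
#' @return An object of class `"mms_band"`.
#' @export
zone_band <- function(zone, intervals = NULL, categories = NULL) {
  zone <- match.arg(zone, ZONES)
  if (is.null(intervals) == is.null(categories)) {
    stop("supply exactly one of `intervals` or `categories`")
  }
  if (!is.null(intervals)) {
    if (inherits(intervals, "mms_interval")) intervals <- list(intervals)
    stopifnot(length(intervals) > 0L,
              all(vapply(intervals, inherits, logical(1), "mms_interval")))
  } else {
    stopifnot(is.character(categories), length(categories) > 0L)
  }
  structure(list(zone = zone, intervals = intervals, categories = categories),
            class = "mms_band")
}

#' Screening parameter specification
#'
#' A monitored parameter: its measurement kind, unit, admissible domain and
#' zone bands. Continuous domains are closed numeric ranges; categorical
#' domains are the admissible label vocabulary (ordinal scales such as the
#' proteinuria dipstick are encoded as ordered category labels).
#'
#' @param name Canonical parameter identifier (unique within a chart).
#' @param kind `"continuous"` or `"categorical"`.
#' @param unit Measurement unit string (may be `""` for categorical scales).
#' @param domain Numeric `c(lower, upper)` for continuous parameters, or a
#'   character vector of admissible labels.
#' @param bands List of [zone_band()] objects. Exactly one green band is
#'   required; orange and red bands are optional (some one-sided laboratory
#'   parameters alert only on elevation).
#' @return An object of class `"mms_parameter"`.
#' @export
parameter_spec <- function(name, kind = c("continuous", "categorical"),
                           unit = "", domain, bands) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (inherits(bands, "mms_band")) bands <- list(bands)
  stopifnot(all(vapply(bands, inherits, logical(1), "mms_band")))
  if (kind == "continuous") {
    stopifnot(is.numeric(domain), length(domain) == 2L, domain[1] < domain[2])
    if (any(vapply(bands, function(b) is.null(b$intervals), logical(1)))) {
      stop("continuous parameter '", name, "' has a categorical band")
    }
  } else {
    stopifnot(is.character(domain), length(domain) >= 1L)
    if (any(vapply(bands, function(b) is.null(b$categories), logical(1)))) {
      stop("categorical parameter '", name, "' has an interval band")
    }
  }
  n_green <- sum(vapply(bands, function(b) b$zone == "green", logical(1)))
  if (n_green != 1L) {
    stop("parameter '", name, "' must have exactly one green band, found ",
         n_green)
  }
  structure(list(name = name, kind = kind, unit = unit,
                 domain = domain, bands = bands),
            class = "mms_parameter")
}

#' Trigger aggregation rule
#'
#' How many simultaneous alert-zone parameters in a single observation round
#' fire a trigger. The default (one red, or two simultaneous oranges) is the
#' CEMACH/MEOWS track-and-trigger convention.
#'
#' @param red Minimum simultaneous red assignments that fire a trigger.
#' @param orange Minimum simultaneous orange assignments that fire a trigger.
#' @return An object of class `"mms_trigger_rule"`.
#' @export
trigger_rule <- function(red = 1L, orange = 2L) {
  red <- as.integer(red); orange <- as.integer(orange)
  stopifnot(length(red) == 1L, length(orange) == 1L, !is.na(red),
            !is.na(orange), red >= 1L, orange >= 1L)
  structure(list(red = red, orange = orange), class = "mms_trigger_rule")
}

#' Screening chart definition
#'
#' A named track-and-trigger instrument: an ordered set of parameter
#' specifications plus the trigger aggregation rule.
#'
#' @param name Chart identifier.
#' @param parameters List of [parameter_spec()] objects with unique names.
#' @param rule A [trigger_rule()].
#' @return An object of class `"mms_chart"`. Parameters are stored as a named
#'   list; access one with `chart_parameter()`.
#' @seealso [mms_chart()], [meows_chart()], [validate_chart()],
#'   [classify_value()]
#' @export
chart_definition <- function(name, parameters, rule = trigger_rule()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.list(parameters), length(parameters) > 0L,
            all(vapply(parameters, inherits, logical(1), "mms_parameter")),
            inherits(rule, "mms_trigger_rule"))
  nms <- vapply(parameters, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    stop("duplicate parameter names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  names(parameters) <- nms
  structure(list(name = name, parameters = parameters, trigger_rule = rule),
            class = "mms_chart")
}

#' Names of the parameters a chart monitors
#' @param chart An `mms_chart`.
#' @return Character vector of parameter names, in chart order.
#' @export
chart_parameters <- function(chart) {
  stopifnot(inherits(chart, "mms_chart"))
  names(chart$parameters)
}

#' Retrieve one parameter specification from a chart
#' @param chart An `mms_chart`.
#' @param name Parameter name.
#' @return The `mms_parameter`; error if the chart does not monitor `name`.
#' @export
chart_parameter <- function(chart, name) {
  stopifnot(inherits(chart, "mms_chart"))
  spec <- chart$parameters[[name]]
  if (is.null(spec)) {
    stop("chart '", chart$name, "' has no parameter '", name, "'")
  }
  spec
}

#' @export
print.mms_chart <- function(x, ...) {
  cat("<mms_chart> ", x$name, "\n", sep = "")
  cat("  trigger rule: >=", x$trigger_rule$red, " red or >=",
      x$trigger_rule$orange, " orange in one observation round\n", sep = "")
  cat("  parameters (", length(x$parameters), "):\n", sep = "")
  for (p in x$parameters) {
    zones <- vapply(p$bands, `[[`, character(1), "zone")
    cat("   - ", p$name, " [", p$kind,
        if (nzchar(p$unit)) paste0(", ", p$unit), "]: ",
        paste(zones, collapse = "/"), "\n", sep = "")
  }
  invisible(x)
}

#' @export
print.mms_parameter <- function(x, ...) {
  cat("<mms_parameter> ", x$name, " (", x$kind,
      if (nzchar(x$unit)) paste0(", ", x$unit), ")\n", sep = "")
  for (b in x$bands) {
    body <- if (!is.null(b$intervals)) {
      paste(vapply(b$intervals, format_interval, character(1)),
            collapse = " U ")
    } else {
      paste(b$categories, collapse = ", ")
    }
    cat("  ", format(b$zone, width = 6), " ", body, "\n", sep = "")
  }
  invisible(x)
}

band_zones <- function(spec) vapply(spec$bands, `[[`, character(1), "zone")

#' Classify a single measurement into a zone
#'
#' Finds the zone band containing `value`. For continuous parameters, a value
#' that falls in a gap between printed thresholds (for example a respiratory
#' rate of 20.5 between the normal band ending at 20 and the orange band
#' starting at 21) resolves to the more severe of the two adjacent bands —
#' the conservative screening convention — unless `gaps = "strict"`.
#'
#' @param spec An [parameter_spec()] object.
#' @param value A single measurement: finite numeric for continuous
#'   parameters, a known category label otherwise.
#' @param gaps `"severe"` (default, conservative gap resolution) or
#'   `"strict"` (a gap value is an error).
#' @return One of [ZONES].
#' @examples
#' chart <- mms_chart()
#' classify_value(chart_parameter(chart, "temperature"), 37)   # "green"
#' classify_value(chart_parameter(chart, "heart_rate"), 110)   # "orange"
#' classify_value(chart_parameter(chart, "systolic_bp"), 170)  # "red"
#' @export
classify_value <- function(spec, value, gaps = c("severe", "strict")) {
  stopifnot(inherits(spec, "mms_parameter"))
  gaps <- match.arg(gaps)

  if (spec$kind == "categorical") {
    if (length(value) != 1L || is.na(value)) {
      stop("parameter '", spec$name, "': value must be a single category label")
    }
    value <- as.character(value)
    if (!value %in% spec$domain) {
      stop("parameter '", spec$name, "': unknown category '", value,
           "' (admissible: ", paste(spec$domain, collapse = ", "), ")")
    }
    for (b in spec$bands) if (value %in% b$categories) return(b$zone)
    stop("parameter '", spec$name, "': category '", value,
         "' not covered by any band")
  }

  if (length(value) != 1L || !is.numeric(value) || !is.finite(value)) {
    stop("parameter '", spec$name, "': value must be a single finite number")
  }
  if (value < spec$domain[1] || value > spec$domain[2]) {
    stop("parameter '", spec$name, "': value ", value,
         " outside admissible domain [", spec$domain[1], ", ",
         spec$domain[2], "] ", spec$unit)
  }

  hits <- character(0)
  for (b in spec$bands) {
    if (any(vapply(b$intervals, in_interval, logical(1), x = value))) {
      hits <- c(hits, b$zone)
    }
  }
  if (length(hits) == 1L) return(hits)
  if (length(hits) > 1L) {
    stop("parameter '", spec$name, "': bands overlap at value ", value,
         " (", paste(hits, collapse = ", "), ")")
  }

  if (gaps == "strict") {
    stop("parameter '", spec$name, "': value ", value,
         " falls in a between-band gap")
  }
  resolve_gap(spec, value)
}

# Gap value: take the more severe of the band nearest below and nearest above.
resolve_gap <- function(spec, value) {
  below_zone <- NA_character_; below_dist <- Inf
  above_zone <- NA_character_; above_dist <- Inf
  for (b in spec$bands) {
    for (iv in b$intervals) {
      if (iv$upper <= value) {           # band ends at or below the value
        d <- value - iv$upper
        if (d < below_dist) { below_dist <- d; below_zone <- b$zone }
      }
      if (iv$lower >= value) {           # band starts at or above the value
        d <- iv$lower - value
        if (d < above_dist) { above_dist <- d; above_zone <- b$zone }
      }
    }
  }
  z <- worst_zone(c(below_zone, above_zone))
  if (is.na(z)) {
    stop("parameter '", spec$name, "': value ", value,
         " has no adjacent band (empty band set?)")
  }
  z
}

#' Validate a chart definition
#'
#' Checks, per parameter: the bands jointly cover the admissible domain
#' (continuous domains are swept on a fine grid plus all band boundaries;
#' categorical domains are enumerated), bands are pairwise disjoint, a green
#' band exists, and a unit is declared for continuous parameters. A chart
#' with no errors guarantees [classify_value()] is total over its domains.
#'
#' @param chart An `mms_chart`.
#' @param gaps Passed to [classify_value()]: under `"severe"` (default) a
#'   between-band gap is resolvable and reported as a note; under `"strict"`
#'   it is a coverage error.
#' @param grid_points Number of sweep points per continuous domain.
#' @return An object of class `"mms_validation"`: a data.frame with columns
#'   `parameter`, `type` (`"error"`/`"note"`), `message`, plus attribute
#'   `ok` (no errors). Its print method summarises.
#' @export
validate_chart <- function(chart, gaps = c("severe", "strict"),
                           grid_points = 501L) {
  stopifnot(inherits(chart, "mms_chart"))
  gaps <- match.arg(gaps)
  rows <- list()
  add <- function(parameter, type, message) {
    rows[[length(rows) + 1L]] <<- data.frame(
      parameter = parameter, type = type, message = message,
      stringsAsFactors = FALSE)
  }

  for (spec in chart$parameters) {
    zones <- band_zones(spec)
    if (!"green" %in% zones) add(spec$name, "error", "no green band")

    if (spec$kind == "categorical") {
      covered <- unlist(lapply(spec$bands, `[[`, "categories"))
      missing <- setdiff(spec$domain, covered)
      if (length(missing)) {
        add(spec$name, "error",
            paste0("uncovered categories: ", paste(missing, collapse = ", ")))
      }
      dup <- covered[duplicated(covered)]
      if (length(dup)) {
        add(spec$name, "error",
            paste0("categories in multiple bands: ",
                   paste(unique(dup), collapse = ", ")))
      }
      next
    }

    if (!nzchar(spec$unit)) add(spec$name, "note", "no unit declared")

    bounds <- unlist(lapply(spec$bands, function(b)
      unlist(lapply(b$intervals, function(iv)
        c(iv$lower, iv$upper)))))
    bounds <- bounds[is.finite(bounds)]
    probe <- sort(unique(c(
      seq(spec$domain[1], spec$domain[2], length.out = grid_points),
      bounds[bounds >= spec$domain[1] & bounds <= spec$domain[2]])))

    n_hit <- vapply(probe, function(v) {
      sum(vapply(spec$bands, function(b)
        any(vapply(b$intervals, in_interval, logical(1), x = v)), logical(1)))
    }, integer(1))

    if (any(n_hit > 1L)) {
      at <- probe[which(n_hit > 1L)[1]]
      add(spec$name, "error", paste0("overlapping bands at value ", at))
    }
    if (any(n_hit == 0L)) {
      gap_vals <- probe[n_hit == 0L]
      msg <- paste0("domain not covered near ",
                    paste(utils::head(signif(gap_vals, 6), 3), collapse = ", "))
      if (gaps == "strict") add(spec$name, "error", msg)
      else add(spec$name, "note",
               paste0(msg, " (resolved to the severe adjacent band)"))
    }
  }

  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(parameter = character(0), type = character(0),
               message = character(0), stringsAsFactors = FALSE)
  structure(out, ok = !any(out$type == "error"), chart = chart$name,
            class = c("mms_validation", "data.frame"))
}

#' @export
print.mms_validation <- function(x, ...) {
  cat("<mms_validation> chart '", attr(x, "chart"), "': ",
      if (attr(x, "ok")) "OK" else "FAILED", "\n", sep = "")
  if (nrow(x)) {
    for (i in seq_len(nrow(x))) {
      cat("  ", x$type[i], " [", x$parameter[i], "] ", x$message[i], "\n",
          sep = "")
    }
  }
  invisible(x)
}
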