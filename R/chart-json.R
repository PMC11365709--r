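# Chart definition file format: JSON with explicit bound-inclusivity flags,
# no string-parsed ranges. Infinite bounds are encoded as null.

band_to_list <- function(b) {
  if (!is.null(b$intervals)) {
    list(zone = b$zone, intervals = lapply(b$intervals, function(x) {
      list(lower = if (is.finite(x$lower)) x$lower else NULL,
           upper = if (is.finite(x$upper)) x$upper else NULL,
           lower_closed = x$lower_closed,
           upper_closed = x$upper_closed)
    }))
  } else {
    list(zone = b$zone, categories = as.list(b$categories))
  }
}

band_from_list <- function(x) {
  if (!is.null(x$intervals)) {
    zone_band(x$zone, intervals = lapply(x$intervals, function(ivl) {
      interval(
        lower = if (is.null(ivl$lower)) -Inf else as.numeric(ivl$lower),
        upper = if (is.null(ivl$upper)) Inf else as.numeric(ivl$upper),
        lower_closed = isTRUE(ivl$lower_closed),
        upper_closed = isTRUE(ivl$upper_closed))
    }))
  } else {
    zone_band(x$zone, categories = as.character(unlist(x$categories)))
  }
}

#' Convert a chart to / from a plain list (the JSON schema)
#'
#' @param chart An `mms_chart`.
#' @return `chart_to_list()`: a nested list mirroring the JSON chart schema.
#' @keywords internal
#' @export
chart_to_list <- function(chart) {
  stopifnot(inherits(chart, "mms_chart"))
  list(
    name = chart$name,
    trigger_rule = list(red = chart$trigger_rule$red,
                        orange = chart$trigger_rule$orange),
    parameters = lapply(unname(chart$parameters), function(p) {
      list(name = p$name, kind = p$kind, unit = p$unit,
           domain = if (p$kind == "continuous") as.list(p$domain)
                    else as.list(p$domain),
           bands = lapply(p$bands, band_to_list))
    }))
}

#' @rdname chart_to_list
#' @param x A nested list in the JSON chart schema.
#' @return `chart_from_list()`: an `mms_chart`.
#' @keywords internal
#' @export
chart_from_list <- function(x) {
  if (is.null(x$name) || is.null(x$parameters)) {
    stop("chart definition must carry 'name' and 'parameters'")
  }
  rule <- if (is.null(x$trigger_rule)) trigger_rule() else
    trigger_rule(red = x$trigger_rule$red, orange = x$trigger_rule$orange)
  params <- lapply(x$parameters, function(p) {
    kind <- match.arg(p$kind, c("continuous", "categorical"))
    domain <- if (kind == "continuous") as.numeric(unlist(p$domain))
              else as.character(unlist(p$domain))
    parameter_spec(p$name, kind, unit = if (is.null(p$unit)) "" else p$unit,
                   domain = domain, bands = lapply(p$bands, band_from_list))
  })
  chart_definition(x$name, params, rule = rule)
}

#' Write a chart definition to a JSON file
#'
#' Charts round-trip losslessly: `read_chart(write_chart(chart, path))`
#' reproduces the chart exactly.
#'
#' @param chart An `mms_chart`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_chart <- function(chart, path) {
  jsonlite::write_json(chart_to_list(chart), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a chart definition from a JSON file
#'
#' @param path Path to a chart JSON file (see the packaged examples under
#'   `system.file("extdata", "charts", package = "mmscreen")`), or a
#'   built-in chart name (`"MMS"`, `"MEOWS"`).
#' @return An `mms_chart`.
#' @export
read_chart <- function(path) {
  if (toupper(path) %in% c("MMS", "MEOWS")) return(builtin_chart(path))
  if (!file.exists(path)) stop("chart file not found: ", path)
  chart_from_list(jsonlite::read_json(path, simplifyVector = FALSE))
}
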