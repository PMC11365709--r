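# CSV / JSON interchange. Dialect: UTF-8, comma-separated, header row
# required, '.' decimal point.

#' Write / read a cohort's long-format observations CSV
#'
#' Columns: `patient_id`, `time_h`, `parameter`, `value` (categorical
#' values as canonical labels).
#'
#' @param cohort List of [patient_record()] objects.
#' @param path CSV file path.
#' @return `write_observations()`: `path`, invisibly.
#'   `read_observations()`: the long-format data.frame.
#' @export
write_observations <- function(cohort, path) {
  rows <- lapply(cohort, function(r)
    cbind(patient_id = r$patient_id, r$observations))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", fileEncoding = "UTF-8")
  need <- c("patient_id", "time_h", "parameter", "value")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("observations CSV lacks column(s): ", paste(missing, collapse = ", "))
  }
  df$time_h <- suppressWarnings(as.numeric(df$time_h))
  bad <- which(is.na(df$time_h))
  if (length(bad)) {
    stop("observations CSV line ", bad[1] + 1L, ": non-numeric time_h")
  }
  df[need]
}

#' Write / read the per-patient metadata CSV
#'
#' Columns: `patient_id`, `delivery_time_h`, `outcome` (1 or 2),
#' `delivery_mode` (normal / lscs / assisted, may be empty).
#'
#' @param cohort List of [patient_record()] objects.
#' @param path CSV file path.
#' @return `write_patients()`: `path`, invisibly. `read_patients()`: a
#'   data.frame.
#' @export
write_patients <- function(cohort, path) {
  df <- data.frame(
    patient_id = vapply(cohort, `[[`, character(1), "patient_id"),
    delivery_time_h = vapply(cohort, `[[`, numeric(1), "delivery_time_h"),
    outcome = vapply(cohort, `[[`, integer(1), "outcome"),
    delivery_mode = vapply(cohort, `[[`, character(1), "delivery_mode"),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_patients
#' @export
read_patients <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", fileEncoding = "UTF-8")
  need <- c("patient_id", "delivery_time_h", "outcome")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("patients CSV lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0L) stop("patients CSV contains no patients")
  df$delivery_time_h <- as.numeric(df$delivery_time_h)
  df$outcome <- as.integer(df$outcome)
  if (any(!df$outcome %in% c(1L, 2L))) {
    stop("patients CSV: outcome must be 1 or 2")
  }
  if (is.null(df$delivery_mode)) df$delivery_mode <- NA_character_
  df$delivery_mode[!nzchar(df$delivery_mode) | is.na(df$delivery_mode)] <-
    NA_character_
  df[c(need, "delivery_mode")]
}

#' Assemble patient records from observation and patient tables
#'
#' @param observations Long-format data.frame as from [read_observations()].
#' @param patients Data.frame as from [read_patients()].
#' @return A list of [patient_record()] objects, one per row of `patients`.
#' @export
assemble_cohort <- function(observations, patients) {
  stray <- setdiff(unique(observations$patient_id), patients$patient_id)
  if (length(stray)) {
    stop("observations for unknown patient(s): ",
         paste(utils::head(stray, 5), collapse = ", "))
  }
  lapply(seq_len(nrow(patients)), function(i) {
    p <- patients[i, ]
    obs <- observations[observations$patient_id == p$patient_id,
                        c("time_h", "parameter", "value"), drop = FALSE]
    if (nrow(obs) == 0L) stop("patient ", p$patient_id, ": no observations")
    obs <- obs[order(obs$time_h), , drop = FALSE]
    patient_record(p$patient_id, obs, delivery_time_h = p$delivery_time_h,
                   outcome = p$outcome, delivery_mode = p$delivery_mode)
  })
}

#' Read a cohort from its observations and patients CSV files
#' @param observations_path,patients_path CSV file paths.
#' @return A list of [patient_record()] objects.
#' @export
read_cohort <- function(observations_path, patients_path) {
  assemble_cohort(read_observations(observations_path),
                  read_patients(patients_path))
}

#' Export trigger summaries as a wide CSV
#'
#' One row per patient: `patient_id`, `triggered`, `first_trigger_time_h`,
#' plus one `worst_<parameter>` column per chart parameter.
#'
#' @param summaries List of `trigger_summary` objects.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_trigger_summaries <- function(summaries, path) {
  params <- sort(unique(unlist(lapply(summaries, function(s)
    names(s$per_parameter_worst)))))
  rows <- lapply(summaries, function(s) {
    worst <- vapply(params, function(p) {
      w <- s$per_parameter_worst[[p]]
      if (is.null(w)) NA_character_ else w
    }, character(1))
    df <- data.frame(patient_id = s$patient_id, triggered = s$triggered,
                     first_trigger_time_h = s$first_trigger_time_h,
                     stringsAsFactors = FALSE)
    for (p in params) df[[paste0("worst_", p)]] <- worst[[p]]
    df
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a 2x2 contingency stanza from CSV or JSON
#'
#' Accepts either a JSON object `{"tp": .., "fp": .., "fn": .., "tn": ..}`
#' or a one-row CSV with columns `tp, fp, fn, tn` — handy for re-analysing
#' published tables without patient-level data.
#'
#' @param path File path (`.json` or `.csv`).
#' @return A [contingency_2x2()].
#' @export
read_contingency <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)[1, ]
  }
  need <- c("tp", "fp", "fn", "tn")
  if (!all(need %in% names(x))) {
    stop("contingency input needs fields tp, fp, fn, tn")
  }
  contingency_2x2(as.numeric(x[["tp"]]), as.numeric(x[["fp"]]),
                  as.numeric(x[["fn"]]), as.numeric(x[["tn"]]))
}

#' Write a diagnostic report to JSON and CSV
#'
#' @param report A `diagnostic_report`.
#' @param json_path,csv_path Output paths (either may be `NULL`).
#' @return Invisibly, the list serialised to JSON.
#' @export
write_report <- function(report, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(report, "diagnostic_report"))
  out <- list(ci_level = report$ci_level,
              counts = unclass(report$counts),
              metrics = report$metrics)
  if (!is.null(json_path)) {
    jsonlite::write_json(out, json_path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  }
  if (!is.null(csv_path)) {
    utils::write.csv(report$metrics, csv_path, row.names = FALSE,
                     quote = FALSE)
  }
  invisible(out)
}
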