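#' Construct and validate a vital-sign stream
#'
#' A vital stream is a tibble of timestamped single-parameter measurements,
#' stably sorted by `(patient_id, timestamp)` (records sharing a patient and
#' timestamp keep their input order). Validation enforces the hard
#' physiologic plausibility bounds of [vital_parameters()]: values must be
#' finite and non-negative, SpO2 in \[0, 100\] percent, temperature in
#' \[25, 45\] degrees Celsius. Out-of-bounds records are rejected loudly, not
#' silently dropped.
#'
#' @param data A data frame with columns `patient_id` (character),
#'   `timestamp` (POSIXct or ISO-8601 string with explicit offset),
#'   `parameter` (one of `vital_parameters()$parameter`), `value` (numeric),
#'   `source` (`"MONITOR"` or `"MANUAL"`).
#' @return A validated, stably sorted tibble of class `vital_stream`.
#' @export
#' @examples
#' vital_stream(data.frame(
#'   patient_id = "p1", timestamp = "2019-01-01T00:00:00Z",
#'   parameter = "HR", value = 80, source = "MONITOR"
#' ))
vital_stream <- function(data = NULL) {
  cols <- c("patient_id", "timestamp", "parameter", "value", "source")
  if (is.null(data) || nrow(data) == 0) {
    out <- tibble::tibble(
      patient_id = character(), timestamp = parse_instant(character()),
      parameter = character(), value = double(), source = character()
    )
    class(out) <- c("vital_stream", class(out))
    return(out)
  }
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    stop_validation(paste0("missing column(s): ",
                           paste(missing_cols, collapse = ", ")))
  }
  data <- tibble::as_tibble(data)[cols]
  data$patient_id <- as.character(data$patient_id)
  data$parameter <- as.character(data$parameter)
  data$source <- as.character(data$source)
  if (is.character(data$timestamp)) {
    data$timestamp <- parse_instant(data$timestamp)
  }
  attr(data$timestamp, "tzone") <- "UTC"
  problems <- validate_vital_rows(data)
  if (length(problems) > 0) {
    stop_validation(c("invalid vital-sign record(s):",
                      stats::setNames(problems, rep("x", length(problems)))))
  }
  ord <- order(data$patient_id, data$timestamp)  # stable in base R
  out <- data[ord, ]
  class(out) <- c("vital_stream", class(out))
  out
}

# returns a character vector of row-level problems ("row <i>: <why>")
validate_vital_rows <- function(data) {
  bounds <- vital_parameters()
  i <- seq_len(nrow(data))
  msgs <- character()
  bad_ts <- is.na(data$timestamp)
  msgs <- c(msgs, sprintf("row %d: unparseable or offset-less timestamp",
                          i[bad_ts]))
  bad_par <- !data$parameter %in% bounds$parameter
  msgs <- c(msgs, sprintf("row %d: unknown parameter '%s'",
                          i[bad_par], data$parameter[bad_par]))
  bad_src <- !data$source %in% SOURCES
  msgs <- c(msgs, sprintf("row %d: unknown source '%s'",
                          i[bad_src], data$source[bad_src]))
  v <- suppressWarnings(as.numeric(data$value))
  bad_num <- !is.finite(v)
  msgs <- c(msgs, sprintf("row %d: non-numeric or non-finite value",
                          i[bad_num]))
  lim <- bounds[match(data$parameter, bounds$parameter), ]
  oob <- !bad_par & !bad_num & (v < lim$min | v > lim$max)
  msgs <- c(msgs, sprintf(
    "row %d: %s value %s outside plausibility bounds [%s, %s]",
    i[oob], data$parameter[oob], data$value[oob], lim$min[oob], lim$max[oob]))
  msgs
}

FLOWSHEET_HEADER <- c("patient_id", "timestamp", "parameter", "value", "source")

#' Read a vital-sign flowsheet CSV
#'
#' Reads the documented flowsheet dialect (UTF-8, comma-separated, RFC-4180
#' quoting) with the exact header
#' `patient_id,timestamp,parameter,value,source`. Timestamps must carry an
#' explicit UTC offset. Invalid rows abort with their line numbers by
#' default; with `skip_invalid = TRUE` they are reported as warnings and
#' dropped — a safety system should be loud about bad input either way.
#'
#' @param path Path to a flowsheet CSV file.
#' @param skip_invalid Drop invalid rows (with a warning) instead of aborting.
#' @return A [vital_stream()] tibble. An empty file (header only) yields an
#'   empty stream.
#' @seealso [write_flowsheet()]
#' @export
read_flowsheet <- function(path, skip_invalid = FALSE) {
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  header <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                                  show_col_types = FALSE))
  if (!identical(header, FLOWSHEET_HEADER)) {
    stop_validation(sprintf(
      "flowsheet header must be exactly '%s', got '%s'",
      paste(FLOWSHEET_HEADER, collapse = ","), paste(header, collapse = ",")))
  }
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    show_col_types = FALSE
  )
  if (nrow(raw) == 0) return(vital_stream())
  raw$timestamp <- parse_instant(raw$timestamp)
  raw$value <- suppressWarnings(as.numeric(raw$value))
  problems <- validate_vital_rows(raw)
  if (length(problems) > 0) {
    bad_rows <- as.integer(sub("^row (\\d+).*", "\\1", problems))
    # +1 for the header line so messages point at file lines
    problems <- sprintf("line %d%s", bad_rows + 1L,
                        sub("^row \\d+", "", problems))
    if (!skip_invalid) {
      stop_validation(c(sprintf("invalid rows in %s:", path),
                        stats::setNames(problems, rep("x", length(problems)))))
    }
    warn(c(sprintf("skipping invalid rows in %s:", path),
           stats::setNames(problems, rep("x", length(problems)))))
    raw <- raw[-unique(bad_rows), ]
  }
  vital_stream(raw)
}

#' Write a vital-sign flowsheet CSV
#'
#' Serializes a validated stream so that [read_flowsheet()] reproduces it
#' exactly: timestamps as ISO-8601 UTC and values at full precision.
#'
#' @param stream A [vital_stream()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_flowsheet <- function(stream, path) {
  stream <- vital_stream(stream)
  out <- tibble::tibble(
    patient_id = stream$patient_id,
    timestamp = format_instant(stream$timestamp),
    parameter = stream$parameter,
    value = format_value(stream$value),
    source = stream$source
  )
  write_csv_safely(out, path)
}

write_csv_safely <- function(df, path) {
  ok <- tryCatch({
    readr::write_csv(df, path)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop_io(sprintf("cannot write %s: %s", path,
                                   conditionMessage(ok)))
  invisible(path)
}

ALERT_LOG_HEADER <- c("patient_id", "fired_at", "criteria", "acknowledgement")

#' Read an alert/acknowledgement log CSV
#'
#' Columns: `patient_id`, `fired_at` (ISO-8601 with offset), `criteria`
#' (semicolon-joined parameter names contributing to the alert), and
#' `acknowledgement` (one of the five outcome labels of [ack_labels()], or
#' empty for an alert still awaiting acknowledgement).
#'
#' @param path Path to an alert log CSV.
#' @return A tibble of alert events sorted by `fired_at`, with list-column
#'   `criteria` expanded into the `n_criteria` count.
#' @seealso [write_alert_log()], [detect()]
#' @export
read_alert_log <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  header <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                                  show_col_types = FALSE))
  if (!identical(header, ALERT_LOG_HEADER)) {
    stop_validation(sprintf(
      "alert log header must be exactly '%s', got '%s'",
      paste(ALERT_LOG_HEADER, collapse = ","), paste(header, collapse = ",")))
  }
  raw <- readr::read_csv(
    path, col_types = readr::cols(.default = readr::col_character()),
    show_col_types = FALSE
  )
  if (nrow(raw) == 0) return(empty_alerts())
  fired <- parse_instant(raw$fired_at)
  if (anyNA(fired)) {
    stop_validation(sprintf("unparseable fired_at on line(s): %s",
                            paste(which(is.na(fired)) + 1L, collapse = ", ")))
  }
  ack <- raw$acknowledgement
  ack[!is.na(ack) & ack == ""] <- NA_character_
  bad <- !is.na(ack) & !ack %in% ack_labels()
  if (any(bad)) {
    stop_validation(sprintf(
      "unknown acknowledgement label(s): %s",
      paste(unique(ack[bad]), collapse = ", ")))
  }
  crits <- strsplit(ifelse(is.na(raw$criteria), "", raw$criteria), ";",
                    fixed = TRUE)
  unknown <- setdiff(unique(unlist(crits)), c(PARAMETERS, ""))
  if (length(unknown) > 0) {
    stop_validation(sprintf("unknown criteria parameter(s): %s",
                            paste(unknown, collapse = ", ")))
  }
  out <- tibble::tibble(
    patient_id = raw$patient_id,
    fired_at = fired,
    criteria = vapply(crits, paste, character(1), collapse = ";"),
    n_criteria = lengths(crits),
    acknowledgement = ack,
    acknowledged_at = parse_instant(rep(NA_character_, nrow(raw)))
  )
  out[order(out$fired_at), ]
}

#' Write an alert log CSV
#'
#' @param alerts An alert tibble as produced by [detect()] or
#'   [read_alert_log()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alert_log <- function(alerts, path) {
  out <- tibble::tibble(
    patient_id = alerts$patient_id,
    fired_at = format_instant(alerts$fired_at),
    criteria = alerts$criteria,
    acknowledgement = ifelse(is.na(alerts$acknowledgement), "",
                             alerts$acknowledgement)
  )
  write_csv_safely(out, path)
}

empty_alerts <- function(with_contributing = FALSE) {
  out <- tibble::tibble(
    patient_id = character(),
    fired_at = parse_instant(character()),
    criteria = character(),
    n_criteria = integer(),
    acknowledgement = character(),
    acknowledged_at = parse_instant(character())
  )
  if (with_contributing) {
    out <- tibble::add_column(out, contributing = list(),
                              .after = "n_criteria")
  }
  out
}
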