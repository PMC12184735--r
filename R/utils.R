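#' Vital-sign parameter vocabulary
#'
#' The seven physiological parameters the system knows about, with units and
#' hard plausibility bounds used at ingest. Values outside the bounds are
#' rejected as implausible, not treated as abnormal-but-real.
#'
#' @return A tibble with columns `parameter`, `unit`, `min`, `max`.
#' @export
#' @examples
#' vital_parameters()
vital_parameters <- function() {
  tibble::tribble(
    ~parameter,     ~unit,         ~min, ~max,
    "SBP",          "mmHg",        0,    Inf,
    "DBP",          "mmHg",        0,    Inf,
    "HR",           "beats/min",   0,    Inf,
    "RR",           "breaths/min", 0,    Inf,
    "SPO2",         "percent",     0,    100,
    "TEMP",         "deg C",       25,   45,
    "URINE_OUTPUT", "mL/hr",       0,    Inf
  )
}

PARAMETERS <- c("SBP", "DBP", "HR", "RR", "SPO2", "TEMP", "URINE_OUTPUT")
SOURCES <- c("MONITOR", "MANUAL")

# ISO-8601 with a mandatory explicit offset (Z or +-hh[:]mm); naive
# timestamps are rejected so that calendar-day bucketing is unambiguous.
TS_REGEX <- paste0(
  "^\\d{4}-\\d{2}-\\d{2}[T ]\\d{2}:\\d{2}(:\\d{2}(\\.\\d+)?)?",
  "(Z|[+-]\\d{2}:?\\d{2})$"
)

parse_instant <- function(x) {
  ok <- !is.na(x) & grepl(TS_REGEX, x)
  out <- rep(as.POSIXct(NA), length(x))
  if (any(ok)) {
    parsed <- readr::parse_datetime(x[ok])
    parsed[is.na(parsed)] <- NA
    out[ok] <- parsed
  }
  attr(out, "tzone") <- "UTC"
  out
}

format_instant <- function(x) {
  format(x, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

format_value <- function(x) {
  # full precision so that write -> read round-trips exactly
  vapply(x, function(v) format(v, digits = 15, trim = TRUE, scientific = FALSE),
         character(1))
}

round_half_up <- function(x) floor(x + 0.5)

stop_validation <- function(msg, ...) {
  abort(msg, class = "emews_validation_error", ...)
}

stop_io <- function(msg, ...) {
  abort(msg, class = "emews_io_error", ...)
}

minutes <- function(x) x * 60

#' @noRd
assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    stop_validation(sprintf("`%s` must be a single finite number", name))
  }
  if (positive && x <= 0) {
    stop_validation(sprintf("`%s` must be positive", name))
  }
  invisible(x)
}
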