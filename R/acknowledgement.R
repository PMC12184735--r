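#' Acknowledgement outcome labels
#'
#' The nurse-facing pop-up offers four response options; a fifth label marks
#' alerts that were never acknowledged. These five labels partition every
#' alert in an audit. `ack_display()` maps a label to its report wording
#' (the pop-up option text by default; the audit-table wording for
#' `MD aware` differs in the source reports and is available as
#' `style = "table"`).
#'
#' @return `ack_labels()`: character vector of the five machine labels, as
#'   written in the alert-log CSV.
#' @export
#' @examples
#' ack_labels()
#' ack_display("md_aware_ongoing")
ack_labels <- function() {
  c("md_aware_ongoing", "will_notify_md", "treatment_provided",
    "not_providing_care", "not_acknowledged")
}

#' @rdname ack_labels
#' @param label One of `ack_labels()`.
#' @param style `"methods"` (pop-up option wording) or `"table"` (audit
#'   table wording).
#' @export
ack_display <- function(label, style = c("methods", "table")) {
  style <- match.arg(style)
  methods_txt <- c(
    md_aware_ongoing = "MD aware, ongoing monitoring",
    will_notify_md = "Will notify MD",
    treatment_provided = "Treatment provided, ongoing monitoring",
    not_providing_care = "Not providing direct care",
    not_acknowledged = "Alert not acknowledged"
  )
  table_txt <- methods_txt
  table_txt[["md_aware_ongoing"]] <- "MD aware, ongoing treatment"
  txt <- if (style == "methods") methods_txt else table_txt
  bad <- setdiff(label, names(txt))
  if (length(bad) > 0) {
    stop_validation(sprintf("unknown acknowledgement label(s): %s",
                            paste(bad, collapse = ", ")))
  }
  unname(txt[label])
}

#' Acknowledge an alert
#'
#' Attaches one of the four active response options to an open alert. An
#' alert can be acknowledged exactly once, never before it fired, and never
#' with the passive `not_acknowledged` label (that label is assigned only by
#' [close_unacknowledged()] at audit time).
#'
#' @param alerts An alert tibble ([detect()] / [read_alert_log()]).
#' @param which Row index of the alert to acknowledge.
#' @param label One of the four active labels of [ack_labels()].
#' @param at Acknowledgement instant (POSIXct); must be `>= fired_at`.
#' @return The alert tibble with the outcome attached.
#' @export
acknowledge <- function(alerts, which, label, at) {
  if (length(which) != 1 || which < 1 || which > nrow(alerts)) {
    stop_validation("`which` must index a single alert row")
  }
  if (!label %in% setdiff(ack_labels(), "not_acknowledged")) {
    stop_validation(sprintf(
      "'%s' is not an active acknowledgement option", label))
  }
  if (!is.na(alerts$acknowledgement[which])) {
    abort(sprintf("alert %d is already acknowledged ('%s')", which,
                  alerts$acknowledgement[which]),
          class = "emews_state_error")
  }
  if (as.numeric(at - alerts$fired_at[which], units = "secs") < 0) {
    stop_validation("acknowledgement cannot precede the alert")
  }
  alerts$acknowledgement[which] <- label
  alerts$acknowledged_at[which] <- at
  alerts
}

#' Close open alerts as not acknowledged
#'
#' Audit-time closure: every alert without an outcome that fired at or
#' before `horizon` is labeled `not_acknowledged`. Acknowledged alerts and
#' alerts firing after the horizon are untouched. No timeout is modeled —
#' closure is an explicit reporting operation.
#'
#' @param alerts An alert tibble.
#' @param horizon Closure instant (POSIXct).
#' @return The alert tibble with open pre-horizon alerts closed.
#' @export
close_unacknowledged <- function(alerts, horizon) {
  open <- is.na(alerts$acknowledgement) & alerts$fired_at <= horizon
  alerts$acknowledgement[open] <- "not_acknowledged"
  alerts
}
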