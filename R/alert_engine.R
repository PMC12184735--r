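#' Phase trigger policy
#'
#' A trigger policy turns criterion flags into alerts. It fires when at
#' least `min_distinct_criteria` distinct parameters have flags inside the
#' half-open lookback window `(t - lookback, t]` anchored at a flag time
#' `t`, and suppresses re-alerting for `refractory` minutes per patient.
#'
#' The three shipped phases mirror the system's development: phase 1 alerts
#' on any single abnormal value instantly; phase 2 keeps the single-criterion
#' trigger but adds a 15-minute delay between alerts; phase 3 requires two
#' or more distinct abnormal parameters within the preceding 30 minutes and
#' a 30-minute window before a subsequent alert can fire.
#'
#' @param phase `"P1"`, `"P2"`, or `"P3"`; sets the defaults below and the
#'   criteria preset of [default_criteria()].
#' @param min_distinct_criteria Minimum count of distinct abnormal
#'   parameters in the window.
#' @param lookback Lookback window, minutes; `0` means only flags at the
#'   anchoring instant count.
#' @param refractory Minimum minutes between consecutive alerts for one
#'   patient.
#' @param criteria A [criteria_config()].
#' @param delay_mode `"refractory"` applies the delay between alerts (the
#'   default reading); `"flag_gap"` is the alternative reading in which an
#'   alert is only eligible when the anchoring flag arrives at least
#'   `refractory` minutes after the previous flag.
#' @return A list of class `phase_config`.
#' @export
#' @examples
#' phase_config("P3")
phase_config <- function(phase = c("P3", "P1", "P2"),
                         min_distinct_criteria = NULL,
                         lookback = NULL,
                         refractory = NULL,
                         criteria = NULL,
                         delay_mode = c("refractory", "flag_gap")) {
  phase <- match.arg(phase)
  delay_mode <- match.arg(delay_mode)
  defaults <- switch(phase,
    P1 = list(min = 1, look = 0, refr = 0),
    P2 = list(min = 1, look = 0, refr = 15),
    P3 = list(min = 2, look = 30, refr = 30)
  )
  cfg <- list(
    phase = phase,
    min_distinct_criteria = min_distinct_criteria %||% defaults$min,
    lookback = lookback %||% defaults$look,
    refractory = refractory %||% defaults$refr,
    criteria = criteria %||% default_criteria(phase),
    delay_mode = delay_mode
  )
  if (cfg$min_distinct_criteria < 1) {
    stop_validation("`min_distinct_criteria` must be >= 1")
  }
  if (cfg$lookback < 0 || cfg$refractory < 0) {
    stop_validation("`lookback` and `refractory` must be >= 0")
  }
  stopifnot(inherits(cfg$criteria, "criteria_config"))
  structure(cfg, class = "phase_config")
}

#' Detect alerts in a vital-sign stream
#'
#' Processes each patient independently in timestamp order. Every flag
#' timestamp `t` is an evaluation anchor: the engine counts distinct
#' parameters with flags in `(t - lookback, t]` and fires an alert at `t`
#' when the count reaches the policy minimum and the patient is outside the
#' refractory period of their previous alert. Simultaneous flags are
#' evaluated together, so at most one alert fires per patient-instant. The
#' contributing set is the most recent flag of each distinct in-window
#' parameter.
#'
#' @param stream A [vital_stream()].
#' @param policy A [phase_config()].
#' @return An alert tibble sorted by `(patient_id, fired_at)`: columns
#'   `patient_id`, `fired_at`, `criteria` (semicolon-joined sorted parameter
#'   names), `n_criteria`, `contributing` (list-column of flag tibbles),
#'   `acknowledgement`, `acknowledged_at`.
#' @seealso [detect_bruteforce()] for the quadratic reference
#'   implementation used as a test oracle.
#' @export
detect <- function(stream, policy) {
  stopifnot(inherits(policy, "phase_config"))
  flags <- flag_stream(stream, policy$criteria)
  alerts_from_flags(flags, policy, engine = "fast")
}

#' Reference alert detection (quadratic scan)
#'
#' Independent re-implementation of the [detect()] contract as a naive scan
#' over all flag pairs. Exists solely as an equivalence oracle for testing
#' the engine; use [detect()] for real streams.
#'
#' @inheritParams detect
#' @return Same contract as [detect()].
#' @export
detect_bruteforce <- function(stream, policy) {
  stopifnot(inherits(policy, "phase_config"))
  flags <- flag_stream(stream, policy$criteria)
  alerts_from_flags(flags, policy, engine = "bruteforce")
}

alerts_from_flags <- function(flags, policy, engine) {
  if (nrow(flags) == 0) return(empty_alerts(with_contributing = TRUE))
  out <- lapply(split(flags, flags$patient_id), function(pf) {
    pf <- pf[order(pf$timestamp), ]
    if (engine == "fast") patient_alerts_fast(pf, policy)
    else patient_alerts_bruteforce(pf, policy)
  })
  out <- purrr::list_rbind(out)
  if (nrow(out) == 0) return(empty_alerts(with_contributing = TRUE))
  out <- out[order(out$patient_id, out$fired_at), ]
  out$acknowledgement <- NA_character_
  out$acknowledged_at <- parse_instant(rep(NA_character_, nrow(out)))
  out
}

# Windowed scan sharing one pass over the flag vector per patient.
patient_alerts_fast <- function(pf, policy) {
  look <- minutes(policy$lookback)
  refr <- minutes(policy$refractory)
  anchors <- unique(pf$timestamp)
  last_alert <- NULL
  rows <- list()
  lo_idx <- 1L
  for (t in seq_along(anchors)) {
    at <- anchors[t]
    if (policy$delay_mode == "flag_gap" && refr > 0) {
      prev <- pf$timestamp[pf$timestamp < at]
      if (length(prev) > 0 &&
          as.numeric(at - max(prev), units = "secs") < refr) next
    }
    if (look > 0) {
      while (pf$timestamp[lo_idx] <= at - look) lo_idx <- lo_idx + 1L
      win <- pf[seq(lo_idx, nrow(pf)), ]
      win <- win[win$timestamp <= at, ]
    } else {
      win <- pf[pf$timestamp == at, ]
    }
    if (length(unique(win$parameter)) < policy$min_distinct_criteria) next
    if (policy$delay_mode == "refractory" && !is.null(last_alert) &&
        as.numeric(at - last_alert, units = "secs") < refr) next
    # most recent flag per distinct parameter (later file order wins ties)
    keep <- !duplicated(win$parameter, fromLast = TRUE)
    contrib <- win[keep, c("patient_id", "timestamp", "parameter", "value",
                           "rule")]
    contrib <- contrib[order(contrib$parameter), ]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      patient_id = pf$patient_id[[1]],
      fired_at = at,
      criteria = paste(contrib$parameter, collapse = ";"),
      n_criteria = nrow(contrib),
      contributing = list(contrib)
    )
    last_alert <- at
  }
  purrr::list_rbind(rows)
}

# Deliberately naive: for every candidate anchor, re-scan every flag.
patient_alerts_bruteforce <- function(pf, policy) {
  look_s <- policy$lookback * 60
  refr_s <- policy$refractory * 60
  anchors <- unique(pf$timestamp)
  alerts <- list()
  last_alert_time <- as.POSIXct(NA)
  for (at in as.list(anchors)) {
    in_window <- logical(nrow(pf))
    for (i in seq_len(nrow(pf))) {
      d <- as.numeric(at - pf$timestamp[i], units = "secs")
      if (look_s > 0) in_window[i] <- d >= 0 && d < look_s
      else in_window[i] <- d == 0
    }
    if (policy$delay_mode == "flag_gap" && refr_s > 0) {
      gap_ok <- TRUE
      best <- NA_real_
      for (i in seq_len(nrow(pf))) {
        d <- as.numeric(at - pf$timestamp[i], units = "secs")
        if (d > 0 && (is.na(best) || d < best)) best <- d
      }
      if (!is.na(best) && best < refr_s) gap_ok <- FALSE
      if (!gap_ok) next
    }
    params <- unique(pf$parameter[in_window])
    if (length(params) < policy$min_distinct_criteria) next
    if (policy$delay_mode == "refractory" && !is.na(last_alert_time)) {
      if (as.numeric(at - last_alert_time, units = "secs") < refr_s) next
    }
    contrib_rows <- integer(0)
    for (p in sort(params)) {
      cand <- which(in_window & pf$parameter == p)
      contrib_rows <- c(contrib_rows, cand[length(cand)])
    }
    contrib <- pf[contrib_rows, c("patient_id", "timestamp", "parameter",
                                  "value", "rule")]
    alerts[[length(alerts) + 1L]] <- tibble::tibble(
      patient_id = pf$patient_id[[1]],
      fired_at = at,
      criteria = paste(contrib$parameter, collapse = ";"),
      n_criteria = nrow(contrib),
      contributing = list(contrib)
    )
    last_alert_time <- at
  }
  purrr::list_rbind(alerts)
}
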