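#' Abnormality criteria configuration
#'
#' Builds the per-parameter trigger table. Defaults are the national
#' maternal-safety-partnership criteria commonly used for maternal early
#' warning, with a fever/hypothermia criterion available for later phases.
#' Every threshold can be overridden, and criteria can be switched off via
#' `enabled`.
#'
#' Boundary semantics are fixed: low bounds flag strictly below
#' (`value < low`) and high bounds strictly above (`value > high`), except
#' the temperature upper bound, which is inclusive (fever is `>= 38` C).
#'
#' @param sbp_low,sbp_high Systolic BP bounds, mmHg.
#' @param dbp_high Diastolic BP upper bound, mmHg (no low bound is used).
#' @param hr_low,hr_high Heart-rate bounds, beats/min.
#' @param rr_low,rr_high Respiratory-rate bounds, breaths/min.
#' @param spo2_low Oxygen-saturation lower bound, percent.
#' @param temp_low,temp_high Temperature bounds, degrees Celsius; the upper
#'   bound is inclusive.
#' @param oliguria_rate Urine-output rate below which output is oliguric,
#'   mL/hr.
#' @param oliguria_duration Minutes over which every urine-output reading
#'   must be below `oliguria_rate` for the criterion to flag.
#' @param enabled Character vector of active parameters.
#' @return A list of class `criteria_config`.
#' @seealso [default_criteria()] for the phase presets.
#' @export
criteria_config <- function(sbp_low = 90, sbp_high = 160,
                            dbp_high = 100,
                            hr_low = 50, hr_high = 120,
                            rr_low = 10, rr_high = 30,
                            spo2_low = 95,
                            temp_low = 36, temp_high = 38,
                            oliguria_rate = 35, oliguria_duration = 120,
                            enabled = c("SBP", "DBP", "HR", "RR", "SPO2",
                                        "URINE_OUTPUT")) {
  cfg <- list(
    sbp_low = sbp_low, sbp_high = sbp_high, dbp_high = dbp_high,
    hr_low = hr_low, hr_high = hr_high,
    rr_low = rr_low, rr_high = rr_high,
    spo2_low = spo2_low,
    temp_low = temp_low, temp_high = temp_high,
    oliguria_rate = oliguria_rate, oliguria_duration = oliguria_duration,
    enabled = as.character(enabled)
  )
  for (nm in setdiff(names(cfg), "enabled")) {
    assert_scalar_number(cfg[[nm]], nm, positive = TRUE)
  }
  pairs <- list(c("sbp_low", "sbp_high"), c("hr_low", "hr_high"),
                c("rr_low", "rr_high"), c("temp_low", "temp_high"))
  for (p in pairs) {
    if (cfg[[p[1]]] >= cfg[[p[2]]]) {
      stop_validation(sprintf("`%s` must be < `%s`", p[1], p[2]))
    }
  }
  bad <- setdiff(cfg$enabled, PARAMETERS)
  if (length(bad) > 0) {
    stop_validation(sprintf("unknown parameter(s) in `enabled`: %s",
                            paste(bad, collapse = ", ")))
  }
  structure(cfg, class = "criteria_config")
}

#' Phase preset criteria
#'
#' The three development phases of the alerting system share one threshold
#' table but differ in which criteria are active: phases 1 and 2 screen
#' SBP, DBP, HR, RR, SpO2 and urine output; phase 3 drops urine output
#' (a manually charted parameter whose inconsistent recording dominated
#' nuisance alerts) and adds the temperature criterion (<36 or >=38 C).
#'
#' @param phase `"P1"`, `"P2"`, or `"P3"`.
#' @param ... Threshold overrides passed to [criteria_config()].
#' @return A `criteria_config`.
#' @export
#' @examples
#' default_criteria("P3")$enabled
default_criteria <- function(phase = c("P3", "P1", "P2"), ...) {
  phase <- match.arg(phase)
  enabled <- switch(phase,
    P1 = ,
    P2 = c("SBP", "DBP", "HR", "RR", "SPO2", "URINE_OUTPUT"),
    P3 = c("SBP", "DBP", "HR", "RR", "SPO2", "TEMP")
  )
  criteria_config(enabled = enabled, ...)
}

# Vectorized rule check shared by evaluate_sample() and flag_stream().
# Returns the violated-rule string per element, or NA when normal.
violated_rule <- function(parameter, value, config) {
  rule <- rep(NA_character_, length(parameter))
  on <- parameter %in% config$enabled
  set <- function(sel, txt) {
    sel <- sel & on & is.na(rule)
    rule[sel] <<- txt
  }
  set(parameter == "SBP" & value < config$sbp_low, "SBP < sbp_low")
  set(parameter == "SBP" & value > config$sbp_high, "SBP > sbp_high")
  set(parameter == "DBP" & value > config$dbp_high, "DBP > dbp_high")
  set(parameter == "HR" & value < config$hr_low, "HR < hr_low")
  set(parameter == "HR" & value > config$hr_high, "HR > hr_high")
  set(parameter == "RR" & value < config$rr_low, "RR < rr_low")
  set(parameter == "RR" & value > config$rr_high, "RR > rr_high")
  set(parameter == "SPO2" & value < config$spo2_low, "SPO2 < spo2_low")
  set(parameter == "TEMP" & value < config$temp_low, "TEMP < temp_low")
  set(parameter == "TEMP" & value >= config$temp_high, "TEMP >= temp_high")
  rule
}

#' Evaluate one vital sample against the criteria
#'
#' Pure per-sample check for every instantaneous criterion. Urine output is
#' duration-qualified and must go through [evaluate_oliguria()] instead.
#'
#' @param sample A one-row [vital_stream()] (or an equivalent one-row data
#'   frame).
#' @param config A [criteria_config()].
#' @return A one-row criterion-flag tibble (`patient_id`, `timestamp`,
#'   `parameter`, `value`, `rule`) if the value is abnormal, else `NULL`.
#' @export
evaluate_sample <- function(sample, config) {
  stopifnot(inherits(config, "criteria_config"))
  sample <- tibble::as_tibble(sample)
  if (nrow(sample) != 1) stop_validation("`sample` must be a single record")
  if (sample$parameter == "URINE_OUTPUT") {
    stop_validation(
      "URINE_OUTPUT is duration-qualified; use evaluate_oliguria()")
  }
  if (!sample$parameter %in% PARAMETERS) {
    stop_validation(sprintf("unknown parameter '%s'", sample$parameter))
  }
  rule <- violated_rule(sample$parameter, sample$value, config)
  if (is.na(rule)) return(NULL)
  tibble::tibble(
    patient_id = as.character(sample$patient_id),
    timestamp = sample$timestamp,
    parameter = sample$parameter,
    value = sample$value,
    rule = rule
  )
}

#' Evaluate the oliguria criterion at an instant
#'
#' Flags when every urine-output reading in the half-open window
#' `[at - oliguria_duration, at)` is below `oliguria_rate` and at least two
#' readings exist in that window. A single low reading never flags: a
#' duration criterion is meaningless from one measurement, and isolated
#' inconsistent urine-output entries were the dominant nuisance-alert source
#' this guard exists for.
#'
#' @param history A [vital_stream()] restricted to one patient's
#'   `URINE_OUTPUT` samples, sorted.
#' @param at The evaluation instant (POSIXct).
#' @param config A [criteria_config()] with `URINE_OUTPUT` enabled.
#' @return A one-row flag tibble, or `NULL`.
#' @export
evaluate_oliguria <- function(history, at, config) {
  stopifnot(inherits(config, "criteria_config"))
  if (!"URINE_OUTPUT" %in% config$enabled) {
    stop_validation("URINE_OUTPUT is not enabled in this configuration")
  }
  if (nrow(history) == 0) return(NULL)
  if (any(history$parameter != "URINE_OUTPUT")) {
    stop_validation("`history` must contain only URINE_OUTPUT samples")
  }
  if (length(unique(history$patient_id)) > 1) {
    stop_validation("`history` must belong to a single patient")
  }
  lo <- at - minutes(config$oliguria_duration)
  in_win <- history$timestamp >= lo & history$timestamp < at
  if (sum(in_win) < 2) return(NULL)
  vals <- history$value[in_win]
  if (!all(vals < config$oliguria_rate)) return(NULL)
  last <- max(which(in_win))
  tibble::tibble(
    patient_id = history$patient_id[[1]],
    timestamp = at,
    parameter = "URINE_OUTPUT",
    value = history$value[last],
    rule = sprintf("URINE_OUTPUT < oliguria_rate for >= %g min",
                   config$oliguria_duration)
  )
}

#' Flag every abnormal sample in a stream
#'
#' Applies [evaluate_sample()] to every instantaneous-parameter sample and,
#' when urine output is enabled, [evaluate_oliguria()] anchored at each
#' urine-output sample time. This is the input the alert engine windows over.
#'
#' @param stream A [vital_stream()].
#' @param config A [criteria_config()].
#' @return A flag tibble sorted by `(patient_id, timestamp)`.
#' @export
flag_stream <- function(stream, config) {
  stopifnot(inherits(config, "criteria_config"))
  stream <- vital_stream(stream)
  inst <- stream[stream$parameter != "URINE_OUTPUT", ]
  rule <- violated_rule(inst$parameter, inst$value, config)
  flags <- tibble::tibble(
    patient_id = inst$patient_id[!is.na(rule)],
    timestamp = inst$timestamp[!is.na(rule)],
    parameter = inst$parameter[!is.na(rule)],
    value = inst$value[!is.na(rule)],
    rule = rule[!is.na(rule)]
  )
  if ("URINE_OUTPUT" %in% config$enabled) {
    uo <- stream[stream$parameter == "URINE_OUTPUT", ]
    uo_flags <- dplyr::group_map(
      dplyr::group_by(uo, .data$patient_id),
      function(h, key) {
        h$patient_id <- key$patient_id
        h <- h[c("patient_id", "timestamp", "parameter", "value", "source")]
        purrr::list_rbind(lapply(seq_len(nrow(h)), function(i) {
          evaluate_oliguria(h, at = h$timestamp[i], config = config) %||%
            tibble::tibble()
        }))
      }
    )
    flags <- dplyr::bind_rows(flags, purrr::list_rbind(uo_flags))
  }
  if (nrow(flags) == 0) {
    return(tibble::tibble(
      patient_id = character(), timestamp = parse_instant(character()),
      parameter = character(), value = double(), rule = character()
    ))
  }
  flags[order(flags$patient_id, flags$timestamp), ]
}
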