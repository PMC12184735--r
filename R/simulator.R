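# local, explicit RNG scope: one seeded generator per simulate call, no
# leakage into (or from) the caller's RNG state
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

rtruncnorm <- function(n, mean, sd, lo, hi) {
  # inverse-CDF draw from a normal truncated to [lo, hi]
  p <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  pmin(pmax(qnorm(p, mean, sd), lo), hi)
}

#' Default baseline physiology for the simulator
#'
#' Per-parameter mean and standard deviation for a stable laboring patient.
#' These are plausible intrapartum values (mild physiologic tachycardia,
#' normotension, normal oxygenation) shipped as configuration, not claims
#' about any study population.
#'
#' @return Tibble with columns `parameter`, `mean`, `sd`.
#' @export
default_baselines <- function() {
  tibble::tribble(
    ~parameter,     ~mean, ~sd,
    "SBP",          118,   9,
    "DBP",          72,    7,
    "HR",           85,    8,
    "RR",           16,    2,
    "SPO2",         98,    1,
    "TEMP",         36.9,  0.2,
    "URINE_OUTPUT", 60,    15
  )
}

# Extreme bands emulating movement/pushing spikes on monitor channels.
# side chosen by fair coin where both bands exist.
default_artifact_bands <- function() {
  list(
    HR   = list(high = c(130, 180), low = c(25, 45)),
    SBP  = list(high = c(165, 220), low = c(50, 85)),
    DBP  = list(high = c(105, 140), low = c(20, 40)),
    SPO2 = list(low = c(70, 90))
  )
}

#' Define a patient scenario for the ward simulator
#'
#' One intrapartum admission: labor of a given duration, optional epidural
#' (which switches BP/HR to 15-minute monitor cadence and adds hourly urine
#' output charting), optional rupture of membranes (hourly temperature
#' thereafter), the immediate 2-hour recovery period after delivery, and an
#' optional deterioration episode that drifts selected parameters linearly
#' from its onset.
#'
#' @param patient_id Opaque identifier.
#' @param admission Admission instant (POSIXct or ISO-8601 string).
#' @param labor_duration Minutes from admission to delivery.
#' @param epidural_at,rom_at Optional instants within
#'   `[admission, delivery]`.
#' @param baseline Tibble like [default_baselines()].
#' @param artifact_rate Probability that a monitor-sourced sample is
#'   replaced by an artifact draw.
#' @param deterioration Optional list
#'   `list(onset =, affected = c(...), drift = c(<param> = units/hour))`.
#' @return A list of class `patient_scenario`.
#' @export
patient_scenario <- function(patient_id, admission, labor_duration,
                             epidural_at = NULL, rom_at = NULL,
                             baseline = default_baselines(),
                             artifact_rate = 0.05,
                             deterioration = NULL) {
  admission <- if (is.character(admission)) parse_instant(admission) else admission
  if (is.na(admission)) stop_validation("`admission` must parse with offset")
  assert_scalar_number(labor_duration, "labor_duration", positive = TRUE)
  delivery_at <- admission + minutes(labor_duration)
  norm_instant <- function(x, name) {
    if (is.null(x)) return(NULL)
    x <- if (is.character(x)) parse_instant(x) else x
    if (is.na(x) || x < admission || x > delivery_at) {
      stop_validation(sprintf("`%s` must lie within [admission, delivery]",
                              name))
    }
    x
  }
  epidural_at <- norm_instant(epidural_at, "epidural_at")
  rom_at <- norm_instant(rom_at, "rom_at")
  if (!is.numeric(artifact_rate) || artifact_rate < 0 || artifact_rate > 1) {
    stop_validation("`artifact_rate` must be in [0, 1]")
  }
  if (!is.null(deterioration)) {
    deterioration$onset <- norm_instant(deterioration$onset,
                                        "deterioration$onset")
    if (!all(deterioration$affected %in% PARAMETERS) ||
        !all(deterioration$affected %in% names(deterioration$drift))) {
      stop_validation(
        "`deterioration` needs affected parameters with matching drift rates")
    }
  }
  structure(list(
    patient_id = as.character(patient_id),
    admission = admission,
    labor_duration = labor_duration,
    delivery_at = delivery_at,
    epidural_at = epidural_at,
    rom_at = rom_at,
    baseline = baseline,
    artifact_rate = artifact_rate,
    deterioration = deterioration
  ), class = "patient_scenario")
}

# Monitoring schedule for one scenario, before values are drawn.
# Protocol: full vitals within the first hour of care then every 4 h;
# post-epidural SBP/DBP/HR every 15 min (plus hourly urine charting, the
# patient being catheterized); post-ROM temperature hourly; after delivery
# the full set every 15 min for 2 h.
scenario_schedule <- function(sc) {
  monitor_params <- c("SBP", "DBP", "HR", "SPO2")
  full_set <- c("SBP", "DBP", "HR", "SPO2", "RR", "TEMP")
  grid <- function(from, to, by_min, params) {
    if (from > to) return(NULL)
    times <- seq(from, to, by = minutes(by_min))
    tidyr::expand_grid(scheduled = times, parameter = params)
  }
  routine_start <- sc$admission + minutes(30)
  parts <- list(
    grid(routine_start, sc$delivery_at, 240, full_set)
  )
  if (!is.null(sc$epidural_at)) {
    parts <- c(parts, list(
      grid(sc$epidural_at, sc$delivery_at, 15, c("SBP", "DBP", "HR")),
      grid(sc$epidural_at, sc$delivery_at, 60, "URINE_OUTPUT")
    ))
  }
  if (!is.null(sc$rom_at)) {
    parts <- c(parts, list(grid(sc$rom_at, sc$delivery_at, 60, "TEMP")))
  }
  parts <- c(parts, list(
    grid(sc$delivery_at, sc$delivery_at + minutes(120), 15, full_set)
  ))
  sch <- dplyr::bind_rows(parts)
  sch$source <- ifelse(sch$parameter %in% monitor_params, "MONITOR", "MANUAL")
  sch <- sch[order(sch$scheduled, sch$parameter), ]
  sch
}

#' Simulate a labor ward
#'
#' Generates a seeded synthetic vital-sign stream for a set of patient
#' scenarios, following the unit's monitoring protocol, together with a
#' ground-truth sidecar for evaluation. Values are drawn from normals
#' truncated at the hard plausibility bounds of [vital_parameters()];
#' manually charted parameters get a 0-10 minute entry-lag jitter;
#' deterioration episodes add linear drift to their affected parameters;
#' monitor samples are replaced by extreme-band artifact draws with the
#' scenario's `artifact_rate` and labeled as artifacts in the truth table.
#' Identical `(scenarios, seed)` give byte-identical output.
#'
#' @param scenarios List of [patient_scenario()] objects.
#' @param seed Integer seed for the simulation's private RNG.
#' @param artifact_bands Per-parameter extreme bands for artifact draws.
#' @return A list with `stream` (a [vital_stream()]), and `truth` (list of
#'   `samples`, a tibble labeling every monitor-sourced sample with
#'   `is_artifact`, and `scenarios`, a tibble with each patient's
#'   `deterioration_onset`).
#' @export
simulate_ward <- function(scenarios, seed,
                          artifact_bands = default_artifact_bands()) {
  if (inherits(scenarios, "patient_scenario")) scenarios <- list(scenarios)
  stopifnot(all(vapply(scenarios, inherits, logical(1), "patient_scenario")))
  with_local_seed(seed, {
    per_patient <- lapply(scenarios, simulate_scenario,
                          artifact_bands = artifact_bands)
  })
  stream <- vital_stream(purrr::list_rbind(lapply(per_patient, `[[`, "samples")))
  truth_samples <- purrr::list_rbind(lapply(per_patient, `[[`, "truth"))
  truth_scenarios <- tibble::tibble(
    patient_id = vapply(scenarios, `[[`, character(1), "patient_id"),
    deterioration_onset = as.POSIXct(vapply(scenarios, function(s) {
      if (is.null(s$deterioration)) NA_real_
      else as.numeric(s$deterioration$onset)
    }, double(1)), origin = "1970-01-01", tz = "UTC")
  )
  list(stream = stream,
       truth = list(samples = truth_samples, scenarios = truth_scenarios))
}

simulate_scenario <- function(sc, artifact_bands) {
  sch <- scenario_schedule(sc)
  n <- nrow(sch)
  bounds <- vital_parameters()
  b <- sc$baseline[match(sch$parameter, sc$baseline$parameter), ]
  lim <- bounds[match(sch$parameter, bounds$parameter), ]
  # draw order is the sorted schedule: deterministic under the call's seed
  value <- rtruncnorm(n, b$mean, b$sd, lim$min, lim$max)
  timestamp <- sch$scheduled
  manual <- sch$source == "MANUAL"
  # whole-second entry lag so serialized timestamps round-trip exactly
  timestamp[manual] <- timestamp[manual] + round(runif(sum(manual), 0, 600))
  if (!is.null(sc$deterioration)) {
    det <- sc$deterioration
    hrs <- as.numeric(timestamp - det$onset, units = "hours")
    aff <- sch$parameter %in% det$affected & hrs > 0
    value[aff] <- value[aff] +
      unname(det$drift[sch$parameter[aff]]) * hrs[aff]
  }
  is_artifact <- rep(FALSE, n)
  monitor <- which(!manual)
  if (sc$artifact_rate > 0 && length(monitor) > 0) {
    hit <- monitor[runif(length(monitor)) < sc$artifact_rate]
    for (i in hit) {
      bands <- artifact_bands[[sch$parameter[i]]]
      if (is.null(bands)) next
      band <- if (length(bands) == 2) {
        if (runif(1) < 0.5) bands$high else bands$low
      } else bands[[1]]
      value[i] <- runif(1, band[1], band[2])
      is_artifact[i] <- TRUE
    }
  }
  value <- pmin(pmax(value, lim$min), lim$max)
  samples <- tibble::tibble(
    patient_id = sc$patient_id,
    timestamp = timestamp,
    parameter = sch$parameter,
    value = round(value, 2),
    source = sch$source
  )
  truth <- tibble::tibble(
    patient_id = sc$patient_id,
    timestamp = timestamp[!manual],
    parameter = sch$parameter[!manual],
    is_artifact = is_artifact[!manual]
  )
  list(samples = samples, truth = truth)
}

#' Generate a reproducible battery of patient scenarios
#'
#' Deterministically allocates `n_patients` among scenario types —
#' uncomplicated labor, labor with epidural analgesia, and a deteriorating
#' (epiduralized) patient whose heart rate and systolic pressure drift
#' upward from mid-labor — then draws admission times and labor durations
#' from the battery's seeded RNG.
#'
#' @param n_patients Number of scenarios.
#' @param mix Named list of fractions `uncomplicated`, `epidural`,
#'   `deterioration` summing to at most 1 (remainder is uncomplicated).
#' @param seed Integer seed.
#' @param start First possible admission instant.
#' @param span_days Admissions are spread uniformly over this many days.
#' @param artifact_rate Artifact probability for every scenario.
#' @return List of [patient_scenario()] objects.
#' @export
scenario_battery <- function(n_patients,
                             mix = list(uncomplicated = 0.3, epidural = 0.6,
                                        deterioration = 0.1),
                             seed = 1,
                             start = "2019-01-01T00:00:00Z",
                             span_days = 14,
                             artifact_rate = 0.05) {
  mix <- utils::modifyList(
    list(uncomplicated = 0, epidural = 0, deterioration = 0), mix)
  if (any(unlist(mix) < 0) || sum(unlist(mix)) > 1 + 1e-9) {
    stop_validation("`mix` fractions must be non-negative and sum to <= 1")
  }
  n_epi <- round(n_patients * mix$epidural)
  n_det <- round(n_patients * mix$deterioration)
  if (n_epi + n_det > n_patients) stop_validation("`mix` over-allocates")
  types <- c(rep("epidural", n_epi), rep("deterioration", n_det),
             rep("uncomplicated", n_patients - n_epi - n_det))
  start <- if (is.character(start)) parse_instant(start) else start
  with_local_seed(seed, {
    admission <- start + round(runif(n_patients, 0, span_days * 1440)) * 60
    labor <- round(runif(n_patients, 240, 720))
    lapply(seq_len(n_patients), function(i) {
      type <- types[i]
      adm <- admission[i]
      det <- NULL
      epi <- NULL
      if (type %in% c("epidural", "deterioration")) epi <- adm
      if (type == "deterioration") {
        det <- list(onset = adm + minutes(round(labor[i] / 2)),
                    affected = c("HR", "SBP"),
                    drift = c(HR = 15, SBP = 12))
      }
      patient_scenario(
        patient_id = sprintf("p%04d", i),
        admission = adm,
        labor_duration = labor[i],
        epidural_at = epi,
        rom_at = adm + minutes(round(labor[i] / 2)),
        artifact_rate = artifact_rate,
        deterioration = det
      )
    })
  })
}
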