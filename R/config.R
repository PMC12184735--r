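#' Default run configuration
#'
#' The layered configuration of the end-to-end pipeline: package defaults,
#' overridden by a YAML file, overridden by explicit arguments, in that
#' precedence order. The resolved configuration is serialized next to every
#' output so a run can be reproduced from its snapshot.
#'
#' @return Nested list: `phase` (policy preset and overrides), `criteria`
#'   (threshold overrides, keys as in [criteria_config()]), `simulator`
#'   (battery settings), `audit` (`timezone`, optional `period`), `seed`,
#'   `log_level`.
#' @export
default_run_config <- function() {
  list(
    phase = list(
      name = "P3",
      min_distinct_criteria = NULL,
      lookback_min = NULL,
      refractory_min = NULL,
      delay_mode = "refractory"
    ),
    criteria = list(),
    simulator = list(
      n_patients = 30,
      mix = list(uncomplicated = 0.3, epidural = 0.6, deterioration = 0.1),
      start = "2019-01-01T00:00:00Z",
      span_days = 14,
      artifact_rate = 0.05
    ),
    audit = list(timezone = "UTC", period = NULL),
    seed = 1,
    log_level = "info"
  )
}

#' Resolve a run configuration
#'
#' @param file Optional YAML file whose top-level blocks override the
#'   defaults.
#' @param overrides Optional nested list applied last (e.g. from CLI flags).
#' @return A fully resolved configuration list.
#' @export
resolve_config <- function(file = NULL, overrides = list()) {
  cfg <- default_run_config()
  if (!is.null(file)) {
    if (!file.exists(file)) stop_io(sprintf("config file not found: %s", file))
    from_file <- yaml::read_yaml(file)
    if (!is.null(from_file)) cfg <- modify_deep(cfg, from_file)
  }
  cfg <- modify_deep(cfg, overrides)
  cfg
}

modify_deep <- function(base, new) {
  for (nm in names(new)) {
    if (is.list(base[[nm]]) && is.list(new[[nm]]) &&
        !is.null(names(new[[nm]]))) {
      base[[nm]] <- modify_deep(base[[nm]], new[[nm]])
    } else {
      base[[nm]] <- new[[nm]]
    }
  }
  base
}

# Build the phase policy (criteria included) from a resolved config.
policy_from_config <- function(cfg) {
  phase <- cfg$phase$name %||% "P3"
  preset <- default_criteria(phase)
  crit_args <- cfg$criteria
  if (length(crit_args) > 0) {
    known <- setdiff(names(formals(criteria_config)), "...")
    bad <- setdiff(names(crit_args), known)
    if (length(bad) > 0) {
      stop_validation(sprintf("unknown criteria key(s): %s",
                              paste(bad, collapse = ", ")))
    }
    base_args <- unclass(preset)
    criteria <- do.call(criteria_config, modify_deep(base_args, crit_args))
  } else {
    criteria <- preset
  }
  phase_config(
    phase,
    min_distinct_criteria = cfg$phase$min_distinct_criteria,
    lookback = cfg$phase$lookback_min,
    refractory = cfg$phase$refractory_min,
    criteria = criteria,
    delay_mode = cfg$phase$delay_mode %||% "refractory"
  )
}
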