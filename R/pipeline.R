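#' Run the full pipeline
#'
#' Simulate (or load) a flowsheet, detect alerts under the configured phase
#' policy, close open alerts, and build the audit report. When `out_dir` is
#' given, all intermediate artifacts are written: `flowsheet.csv`,
#' `truth.csv`, `alerts.csv`, `report.json`, and the resolved configuration
#' snapshot `config.yaml`. Deterministic under a fixed `cfg$seed`:
#' re-running from the snapshot reproduces every file byte-identically.
#'
#' @param cfg A resolved configuration from [resolve_config()].
#' @param flowsheet Optional path to an existing flowsheet CSV; when `NULL`
#'   the simulator generates one.
#' @param out_dir Optional output directory.
#' @return The `audit_report`, invisibly carrying the alerts as attribute
#'   `"alerts"` and the stream as `"stream"`.
#' @export
#' @examples
#' \donttest{
#' cfg <- resolve_config(overrides = list(
#'   seed = 7, simulator = list(n_patients = 5, span_days = 3)
#' ))
#' run_pipeline(cfg)
#' }
run_pipeline <- function(cfg = resolve_config(), flowsheet = NULL,
                         out_dir = NULL) {
  policy <- policy_from_config(cfg)
  sim <- cfg$simulator
  truth <- NULL
  if (is.null(flowsheet)) {
    battery <- scenario_battery(
      n_patients = sim$n_patients, mix = sim$mix, seed = cfg$seed,
      start = sim$start, span_days = sim$span_days,
      artifact_rate = sim$artifact_rate
    )
    ward <- simulate_ward(battery, seed = cfg$seed)
    stream <- ward$stream
    truth <- ward$truth
  } else {
    stream <- read_flowsheet(flowsheet)
  }
  period <- cfg$audit$period
  if (is.null(period)) {
    if (is.null(flowsheet)) {
      p0 <- parse_instant(sim$start)
      period <- c(p0, p0 + sim$span_days * 86400 + 86400 - 1)
    } else if (nrow(stream) > 0) {
      period <- range(stream$timestamp)
    } else {
      stop_validation("empty flowsheet and no audit period configured")
    }
  } else if (is.character(period)) {
    period <- parse_instant(period)
  }
  alerts <- detect(stream, policy)
  alerts <- close_unacknowledged(alerts, horizon = period[2])
  report <- build_report(alerts, period, tz = cfg$audit$timezone %||% "UTC")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_flowsheet(stream, file.path(out_dir, "flowsheet.csv"))
    if (!is.null(truth)) {
      tt <- truth$samples
      tt$timestamp <- format_instant(tt$timestamp)
      write_csv_safely(tt, file.path(out_dir, "truth.csv"))
    }
    write_alert_log(alerts, file.path(out_dir, "alerts.csv"))
    write_report_json(report, file.path(out_dir, "report.json"))
    yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
  }
  attr(report, "alerts") <- alerts
  attr(report, "stream") <- stream
  invisible(report)
}

#' Serialize an audit report to JSON
#'
#' @param report An `audit_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  out <- list(
    period = format_instant(report$period),
    tz = report$tz,
    n_alerts = report$n_alerts,
    n_days = report$n_days,
    alerts_per_day_mean = report$alerts_per_day_mean,
    alerts_per_day_mean_display = report$alerts_per_day_mean_display,
    alerts_per_day_range = report$alerts_per_day_range,
    ack_table = report$ack_table,
    criterion_attribution = report$criterion_attribution
  )
  json <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA,
                           dataframe = "rows", pretty = TRUE)
  ok <- tryCatch({ writeLines(json, path); TRUE }, error = function(e) e)
  if (!isTRUE(ok)) stop_io(sprintf("cannot write %s", path))
  invisible(path)
}

#' Command-line entry point
#'
#' Thin argument-parsing layer over the package functions, exposed so the
#' installed `emews` script (see `inst/cli/emews.R`) stays a two-liner.
#' Subcommands: `simulate`, `detect`, `audit`, `compare`, `run`.
#'
#' @param args Character vector of command-line arguments (subcommand
#'   first).
#' @return Integer exit status: 0 success, 2 validation error, 3 I/O error.
#' @export
emews_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    dispatch_cli(args)
    0L
  },
  emews_validation_error = function(e) {
    message("validation error: ", conditionMessage(e)); 2L
  },
  emews_io_error = function(e) {
    message("I/O error: ", conditionMessage(e)); 3L
  })
  status
}

dispatch_cli <- function(args) {
  if (length(args) == 0) {
    message("usage: emews <simulate|detect|audit|compare|run> [options]")
    return(invisible())
  }
  cmd <- args[1]
  rest <- args[-1]
  opts <- parse_cli_options(cmd, rest)
  switch(cmd,
    simulate = cli_simulate(opts),
    detect = cli_detect(opts),
    audit = cli_audit(opts),
    compare = cli_compare(opts),
    run = cli_run(opts),
    stop_validation(sprintf("unknown subcommand '%s'", cmd))
  )
  invisible()
}

parse_cli_options <- function(cmd, rest) {
  ol <- function(flag, type, default = NULL, help = "") {
    optparse::make_option(flag, type = type, default = default, help = help)
  }
  spec <- switch(cmd,
    simulate = list(
      ol("--n-patients", "integer", 30L), ol("--seed", "integer", 1L),
      ol("--span-days", "integer", 14L),
      ol("--artifact-rate", "double", 0.05),
      ol("--out-flowsheet", "character"), ol("--out-truth", "character")
    ),
    detect = list(
      ol("--flowsheet", "character"), ol("--config", "character"),
      ol("--phase", "character", "P3"), ol("--out", "character")
    ),
    audit = list(
      ol("--alerts", "character"), ol("--period", "character"),
      ol("--tz", "character", "UTC"), ol("--out", "character")
    ),
    compare = list(
      ol("--flowsheet", "character"), ol("--phases", "character", "P1,P2,P3"),
      ol("--period", "character"), ol("--out", "character")
    ),
    run = list(
      ol("--config", "character"), ol("--seed", "integer"),
      ol("--out-dir", "character", "emews-run")
    ),
    list()
  )
  optparse::parse_args(optparse::OptionParser(option_list = spec),
                       args = rest)
}

split_period <- function(x) {
  if (is.null(x)) stop_validation("--period is required (start:end ISO dates)")
  parts <- strsplit(x, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2) {
    stop_validation("--period must be <start-date>:<end-date>")
  }
  parse_instant(c(paste0(parts[1], "T00:00:00Z"),
                  paste0(parts[2], "T23:59:59Z")))
}

cli_simulate <- function(o) {
  battery <- scenario_battery(o$`n-patients`, seed = o$seed,
                              span_days = o$`span-days`,
                              artifact_rate = o$`artifact-rate`)
  ward <- simulate_ward(battery, seed = o$seed)
  if (!is.null(o$`out-flowsheet`)) {
    write_flowsheet(ward$stream, o$`out-flowsheet`)
  }
  if (!is.null(o$`out-truth`)) {
    tt <- ward$truth$samples
    tt$timestamp <- format_instant(tt$timestamp)
    write_csv_safely(tt, o$`out-truth`)
  }
  message(sprintf("simulated %d samples for %d patients",
                  nrow(ward$stream), o$`n-patients`))
}

cli_detect <- function(o) {
  if (is.null(o$flowsheet) || is.null(o$out)) {
    stop_validation("detect requires --flowsheet and --out")
  }
  cfg <- resolve_config(o$config,
                        overrides = list(phase = list(name = o$phase)))
  stream <- read_flowsheet(o$flowsheet)
  alerts <- detect(stream, policy_from_config(cfg))
  write_alert_log(alerts, o$out)
  message(sprintf("%d alerts written to %s", nrow(alerts), o$out))
}

cli_audit <- function(o) {
  if (is.null(o$alerts) || is.null(o$out)) {
    stop_validation("audit requires --alerts and --out")
  }
  period <- split_period(o$period)
  alerts <- read_alert_log(o$alerts)
  alerts <- close_unacknowledged(alerts, horizon = period[2])
  report <- build_report(alerts, period, tz = o$tz)
  write_report_json(report, o$out)
  message(sprintf("report written to %s", o$out))
}

cli_compare <- function(o) {
  if (is.null(o$flowsheet)) stop_validation("compare requires --flowsheet")
  period <- split_period(o$period)
  phases <- strsplit(o$phases, ",", fixed = TRUE)[[1]]
  stream <- read_flowsheet(o$flowsheet)
  policies <- stats::setNames(lapply(phases, phase_config), phases)
  reports <- compare_phases(stream, policies, period)
  for (nm in names(reports)) {
    cat(sprintf("== %s ==\n", nm))
    print(reports[[nm]])
  }
  if (!is.null(o$out)) {
    summary <- lapply(reports, function(r) list(
      n_alerts = r$n_alerts, alerts_per_day_mean = r$alerts_per_day_mean))
    json <- jsonlite::toJSON(summary, auto_unbox = TRUE, digits = NA,
                             pretty = TRUE)
    writeLines(json, o$out)
  }
}

cli_run <- function(o) {
  overrides <- list()
  if (!is.null(o$seed)) overrides$seed <- o$seed
  cfg <- resolve_config(o$config, overrides = overrides)
  report <- run_pipeline(cfg, out_dir = o$`out-dir`)
  print(report)
  message(sprintf("artifacts written to %s", o$`out-dir`))
}
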