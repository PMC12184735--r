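# shared fixtures: everything is built in code at test time

t0 <- as.POSIXct("2019-01-01 00:00:00", tz = "UTC")

at_min <- function(m) t0 + m * 60

parse_ts <- function(x) as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

# quick stream builder: samples at minute offsets
mk_stream <- function(patient_id, minute, parameter, value,
                      source = "MONITOR") {
  vital_stream(data.frame(
    patient_id = patient_id, timestamp = at_min(minute),
    parameter = parameter, value = value, source = source
  ))
}

# random small stream mixing normal and abnormal values across parameters;
# used by the engine property and oracle-equivalence suites
random_stream <- function(n, n_patients = 2, horizon_min = 120) {
  params <- c("SBP", "DBP", "HR", "RR", "SPO2", "TEMP", "URINE_OUTPUT")
  p <- sample(params, n, replace = TRUE)
  v <- vapply(p, function(x) {
    switch(x,
      SBP = runif(1, 60, 200), DBP = runif(1, 40, 130),
      HR = runif(1, 30, 160), RR = runif(1, 5, 40),
      SPO2 = runif(1, 85, 100), TEMP = runif(1, 35, 39.5),
      URINE_OUTPUT = runif(1, 5, 100)
    )
  }, double(1))
  mk_stream(
    patient_id = sample(paste0("p", seq_len(n_patients)), n, replace = TRUE),
    minute = sample(0:horizon_min, n, replace = TRUE),
    parameter = p, value = round(v, 1)
  )
}

# the five printed acknowledgement counts of the source audit table
table1_counts <- c(
  md_aware_ongoing = 1368L, will_notify_md = 751L,
  treatment_provided = 425L, not_providing_care = 86L,
  not_acknowledged = 13L
)

alert_cols <- c("patient_id", "fired_at", "criteria", "n_criteria")
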