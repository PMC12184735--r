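test_that("simulation is byte-identical under a fixed seed", {
  b <- scenario_battery(5, seed = 11)
  w1 <- simulate_ward(b, seed = 42)
  w2 <- simulate_ward(b, seed = 42)
  expect_identical(w1, w2)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_flowsheet(w1$stream, f1)
  write_flowsheet(w2$stream, f2)
  expect_identical(readLines(f1), readLines(f2))
  # and the simulator does not disturb the caller's RNG
  set.seed(1); before <- runif(3)
  set.seed(1); invisible(simulate_ward(b, seed = 42)); after <- runif(3)
  expect_identical(before, after)
})

test_that("monitoring cadences follow the ward protocol", {
  sc <- patient_scenario("p1", "2019-01-01T00:00:00Z", labor_duration = 120,
                         epidural_at = "2019-01-01T00:00:00Z",
                         artifact_rate = 0)
  w <- simulate_ward(list(sc), seed = 1)
  s <- w$stream
  delivery <- at_min(120)
  # epidural: SBP every 15 min over the 120-min labor -> 9 scheduled samples
  sbp_labor <- s[s$parameter == "SBP" & s$timestamp <= delivery, ]
  expect_gte(nrow(sbp_labor), 8)
  # post-delivery: full set every 15 min for 2 h
  post_rr <- s[s$parameter == "RR" & s$timestamp > delivery, ]
  expect_gte(nrow(post_rr), 8)
  expect_true(all(s$source[s$parameter %in% c("RR", "TEMP")] == "MANUAL"))
  expect_true(all(s$source[s$parameter %in% c("SBP", "DBP", "HR", "SPO2")]
                  == "MONITOR"))

  # no ROM, so no hourly temperature chain during labor beyond the
  # 4-hourly routine set (which does not recur within a 2-h labor)
  temp_labor <- s[s$parameter == "TEMP" & s$timestamp <= delivery, ]
  expect_lte(nrow(temp_labor), 2)

  # ROM adds hourly temperature
  sc_rom <- patient_scenario("p2", "2019-01-01T00:00:00Z",
                             labor_duration = 360,
                             rom_at = "2019-01-01T01:00:00Z",
                             artifact_rate = 0)
  w2 <- simulate_ward(list(sc_rom), seed = 1)
  temp2 <- w2$stream[w2$stream$parameter == "TEMP" &
                     w2$stream$timestamp <= at_min(360 + 10), ]
  expect_gte(nrow(temp2), 6)
})

test_that("artifact labels are exact at rate 0 and calibrated at rate 0.05", {
  sc0 <- patient_scenario("p1", "2019-01-01T00:00:00Z", labor_duration = 240,
                          epidural_at = "2019-01-01T00:00:00Z",
                          artifact_rate = 0)
  w0 <- simulate_ward(list(sc0), seed = 5)
  expect_false(any(w0$truth$samples$is_artifact))

  # ~10,500 monitor samples across 30 long epidural labors
  scs <- lapply(1:30, function(i) {
    patient_scenario(sprintf("p%02d", i), "2019-01-01T00:00:00Z",
                     labor_duration = 1440,
                     epidural_at = "2019-01-01T00:00:00Z",
                     artifact_rate = 0.05)
  })
  w <- simulate_ward(scs, seed = 2026)
  lab <- w$truth$samples$is_artifact
  expect_gt(length(lab), 10000)
  se <- sqrt(0.05 * 0.95 / length(lab))
  expect_lt(abs(mean(lab) - 0.05), 3 * se)
  # manual samples are never artifacts (they are not even in the table)
  expect_true(all(w$truth$samples$parameter %in%
                  c("SBP", "DBP", "HR", "SPO2")))
})

test_that("deterioration drift is recoverable by a linear fit", {
  onset <- "2019-01-01T06:00:00Z"
  sc <- patient_scenario(
    "p1", "2019-01-01T00:00:00Z", labor_duration = 720,
    epidural_at = "2019-01-01T00:00:00Z", artifact_rate = 0,
    deterioration = list(onset = onset, affected = c("HR", "SBP"),
                         drift = c(HR = 15, SBP = 12))
  )
  w <- simulate_ward(list(sc), seed = 9)
  s <- w$stream
  hr <- s[s$parameter == "HR" & s$timestamp > parse_ts(onset), ]
  hrs <- as.numeric(hr$timestamp - parse_ts(onset), units = "hours")
  fit <- lm(hr$value ~ hrs)
  est <- coef(summary(fit))["hrs", ]
  expect_lt(abs(est["Estimate"] - 15), 2 * est["Std. Error"])
})

test_that("a benign ward with no artifacts raises no phase-3 alerts", {
  scs <- scenario_battery(6, mix = list(uncomplicated = 0.5, epidural = 0.5),
                          seed = 12, artifact_rate = 0)
  w <- simulate_ward(scs, seed = 12)
  expect_equal(nrow(detect(w$stream, phase_config("P3"))), 0)
})

test_that("battery composition is an exact deterministic allocation", {
  b <- scenario_battery(100, mix = list(epidural = 0.7), seed = 3)
  n_epi <- sum(vapply(b, function(s) !is.null(s$epidural_at), logical(1)))
  n_det <- sum(vapply(b, function(s) !is.null(s$deterioration), logical(1)))
  expect_equal(n_epi, 70)
  expect_equal(n_det, 0)
  b10 <- scenario_battery(10, mix = list(uncomplicated = 1), seed = 3)
  expect_true(all(vapply(b10, function(s) is.null(s$deterioration),
                         logical(1))))
  expect_identical(scenario_battery(10, seed = 8), scenario_battery(10, seed = 8))
  expect_error(scenario_battery(10, mix = list(epidural = 0.8,
                                               deterioration = 0.5)),
               class = "emews_validation_error")
})

test_that("scenario invariants are enforced", {
  expect_error(patient_scenario("p", "2019-01-01T00:00:00Z", 240,
                                epidural_at = "2019-01-02T00:00:00Z"),
               class = "emews_validation_error")
  expect_error(patient_scenario("p", "2019-01-01T00:00:00Z", 240,
                                artifact_rate = 1.5),
               class = "emews_validation_error")
  expect_error(patient_scenario("p", "2019-01-01", 240),
               class = "emews_validation_error")
})
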