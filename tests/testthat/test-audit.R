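test_that("the printed acknowledgement table is reproduced exactly", {
  log <- table1_alert_log(table1_counts)
  # 2643 alerts a minute apart span 2 days
  report <- build_report(log, c("2019-01-01T00:00:00Z",
                                "2019-01-02T23:59:59Z"))
  expect_equal(report$n_alerts, 2643)
  expect_equal(sum(report$ack_table$count), 2643)
  got <- setNames(report$ack_table$percent_display, report$ack_table$outcome)
  expect_identical(got[["md_aware_ongoing"]], "52")
  expect_identical(got[["will_notify_md"]], "28")
  expect_identical(got[["treatment_provided"]], "16")
  expect_identical(got[["not_providing_care"]], "3")
  expect_identical(got[["not_acknowledged"]], "<1")
})

test_that("daily mean and range follow the calendar-day convention", {
  # 10 alerts over 2 days, 5 per day
  fired <- c(at_min(seq(0, 4) * 60), at_min(1440 + seq(0, 4) * 60))
  log <- tibble::tibble(
    patient_id = paste0("p", 1:10), fired_at = fired,
    criteria = "HR", n_criteria = 1L,
    acknowledgement = "md_aware_ongoing", acknowledged_at = fired
  )
  r <- build_report(log, c("2019-01-01T00:00:00Z", "2019-01-02T23:59:59Z"))
  expect_equal(r$alerts_per_day_mean, 5)
  expect_identical(r$alerts_per_day_mean_display, "5.0")
  expect_equal(r$alerts_per_day_range, c(5L, 5L))
  # mean * days == n exactly before display rounding
  expect_equal(r$alerts_per_day_mean * r$n_days, r$n_alerts)
  # zero-alert days enter both mean and range
  r2 <- build_report(log, c("2019-01-01T00:00:00Z", "2019-01-05T23:59:59Z"))
  expect_equal(r2$alerts_per_day_mean, 2)
  expect_equal(r2$alerts_per_day_range, c(0L, 5L))
})

test_that("degenerate one-alert log normalizes to 100% in one row", {
  log <- table1_alert_log(c(will_notify_md = 1L))
  r <- build_report(log, c("2019-01-01T00:00:00Z", "2019-01-01T23:59:59Z"))
  tab <- r$ack_table
  expect_equal(tab$percent[tab$outcome == "will_notify_md"], 100L)
  expect_true(all(tab$count[tab$outcome != "will_notify_md"] == 0))
  expect_true(all(tab$percent[tab$outcome != "will_notify_md"] == 0L))
})

test_that("integer percentages conserve counts and nearly conserve 100", {
  set.seed(31)
  for (i in 1:25) {
    counts <- setNames(as.integer(rmultinom(1, sample(50:3000, 1),
                                            prob = runif(5, 0.01, 1))),
                       ack_labels())
    log <- table1_alert_log(counts)
    r <- build_report(log, c("2019-01-01T00:00:00Z",
                             "2019-01-03T23:59:59Z"))
    expect_equal(sum(r$ack_table$count), sum(counts))
    expect_gte(sum(r$ack_table$percent), 95)
    expect_lte(sum(r$ack_table$percent), 105)
  }
})

test_that("criterion attribution counts alerts, not flags", {
  log <- tibble::tibble(
    patient_id = c("a", "b", "c"),
    fired_at = at_min(c(0, 10, 20)),
    criteria = c("HR;SBP", "HR", "SPO2"),
    n_criteria = c(2L, 1L, 1L),
    acknowledgement = "md_aware_ongoing",
    acknowledged_at = at_min(c(1, 11, 21))
  )
  r <- build_report(log, c("2019-01-01T00:00:00Z", "2019-01-01T23:59:59Z"))
  att <- setNames(r$criterion_attribution$fraction,
                  r$criterion_attribution$parameter)
  expect_equal(att[["HR"]], 2 / 3)
  expect_equal(att[["SBP"]], 1 / 3)
  expect_equal(att[["SPO2"]], 1 / 3)
  expect_true(all(r$criterion_attribution$fraction >= 0 &
                  r$criterion_attribution$fraction <= 1))
})

test_that("reports refuse open alerts and out-of-period alerts", {
  log <- table1_alert_log(c(will_notify_md = 2L))
  open <- log
  open$acknowledgement[1] <- NA_character_
  expect_error(build_report(open, c("2019-01-01T00:00:00Z",
                                    "2019-01-01T23:59:59Z")),
               class = "emews_validation_error")
  expect_error(build_report(log, c("2019-02-01T00:00:00Z",
                                   "2019-02-02T23:59:59Z")),
               class = "emews_validation_error")
})

test_that("phase comparison reports fewer alerts under the stricter policy", {
  # heavy isolated single-channel artifacts: the phase-1 trigger fires on
  # each, the phase-3 two-distinct-criteria trigger never does
  n <- 40
  s <- mk_stream("p1", seq(0, by = 60, length.out = n), rep("HR", n),
                 130 + seq_len(n) %% 5)
  period <- c("2019-01-01T00:00:00Z", "2019-01-02T23:59:59Z")
  crit <- default_criteria("P3")
  reports <- compare_phases(
    s,
    list(P1 = phase_config("P1", criteria = crit),
         P3 = phase_config("P3", criteria = crit)),
    period
  )
  expect_equal(reports$P1$n_alerts, n)
  expect_equal(reports$P3$n_alerts, 0)
  expect_lt(reports$P3$n_alerts, reports$P1$n_alerts)
  # engine monotonicity carries over to the report on any stream
  set.seed(21)
  s2 <- random_stream(60)
  r2 <- compare_phases(
    s2, list(P1 = phase_config("P1", criteria = crit),
             P3 = phase_config("P3", criteria = crit)),
    period
  )
  expect_lte(r2$P3$n_alerts, r2$P1$n_alerts)
  # empty stream: all policies report zero
  r0 <- compare_phases(vital_stream(), list(P1 = phase_config("P1")), period)
  expect_equal(r0$P1$n_alerts, 0)
  expect_equal(r0$P1$alerts_per_day_mean, 0)
})
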