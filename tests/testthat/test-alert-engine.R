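test_that("phase presets encode the deployed trigger policies", {
  p1 <- phase_config("P1"); p2 <- phase_config("P2"); p3 <- phase_config("P3")
  expect_equal(c(p1$min_distinct_criteria, p1$lookback, p1$refractory),
               c(1, 0, 0))
  expect_equal(c(p2$min_distinct_criteria, p2$lookback, p2$refractory),
               c(1, 0, 15))
  expect_equal(c(p3$min_distinct_criteria, p3$lookback, p3$refractory),
               c(2, 30, 30))
})

test_that("single-criterion policy fires once per abnormal value", {
  s <- mk_stream("p1", 0, "HR", 130)
  a <- detect(s, phase_config("P1"))
  expect_equal(nrow(a), 1)
  expect_equal(a$n_criteria, 1L)
  expect_identical(a$criteria, "HR")
})

test_that("two-criteria policy ignores isolated and repeated single-channel flags", {
  p3 <- phase_config("P3")
  # one isolated abnormal HR: no alert
  expect_equal(nrow(detect(mk_stream("p1", 0, "HR", 130), p3)), 0)
  # two HR flags 10 min apart: still one distinct parameter, no alert
  s <- mk_stream("p1", c(0, 10), c("HR", "HR"), c(130, 135))
  expect_equal(nrow(detect(s, p3)), 0)
  # HR at t=0 plus SBP at t=20: two distinct parameters within 30 min
  s2 <- mk_stream("p1", c(0, 20), c("HR", "SBP"), c(130, 170))
  a <- detect(s2, p3)
  expect_equal(nrow(a), 1)
  expect_identical(a$fired_at, at_min(20))
  expect_identical(a$criteria, "HR;SBP")
  # the same pair 31 min apart is outside the lookback
  s3 <- mk_stream("p1", c(0, 31), c("HR", "SBP"), c(130, 170))
  expect_equal(nrow(detect(s3, p3)), 0)
})

test_that("15-minute refractory spaces single-criterion alerts (frozen walk)", {
  # brute-force walk of the rule: flags at 0,5,10,20; alert at 0; 5 and 10
  # are inside the 15-min refractory; 20 - 0 >= 15 fires again
  s <- mk_stream("p1", c(0, 5, 10, 20), rep("HR", 4), c(130, 131, 132, 133))
  a <- detect(s, phase_config("P2"))
  expect_identical(a$fired_at, at_min(c(0, 20)))
  expect_identical(detect_bruteforce(s, phase_config("P2"))$fired_at,
                   at_min(c(0, 20)))
})

test_that("simultaneous flags yield at most one alert per patient-instant", {
  s <- mk_stream("p1", c(0, 0, 0), c("HR", "SBP", "SPO2"), c(130, 170, 90))
  for (ph in c("P1", "P3")) {
    a <- detect(s, phase_config(ph))
    expect_equal(nrow(a), 1)
  }
  a3 <- detect(s, phase_config("P3"))
  expect_identical(a3$criteria, "HR;SBP;SPO2")
})

test_that("contributing set is the most recent flag per distinct parameter", {
  s <- mk_stream("p1", c(0, 10, 20), c("HR", "HR", "SBP"), c(130, 140, 170))
  a <- detect(s, phase_config("P3"))
  expect_equal(nrow(a), 1)
  contrib <- a$contributing[[1]]
  expect_equal(contrib$value[contrib$parameter == "HR"], 140)
})

test_that("patients are processed independently", {
  s1 <- mk_stream("a", c(0, 20), c("HR", "SBP"), c(130, 170))
  s2 <- mk_stream("b", c(5, 15), c("RR", "SPO2"), c(35, 90))
  both <- vital_stream(rbind(as.data.frame(s1), as.data.frame(s2)))
  p3 <- phase_config("P3")
  sep <- rbind(as.data.frame(detect(s1, p3)[alert_cols]),
               as.data.frame(detect(s2, p3)[alert_cols]))
  expect_equal(as.data.frame(detect(both, p3)[alert_cols]), sep,
               ignore_attr = TRUE)
})

test_that("engine matches the brute-force oracle on random streams", {
  set.seed(4242)
  policies <- list(phase_config("P1"), phase_config("P2"), phase_config("P3"))
  for (i in 1:180) {
    s <- random_stream(n = sample(5:40, 1))
    for (pol in policies) {
      d <- detect(s, pol)
      b <- detect_bruteforce(s, pol)
      expect_equal(as.data.frame(d[alert_cols]),
                   as.data.frame(b[alert_cols]),
                   label = sprintf("case %d phase %s", i, pol$phase))
    }
  }
})

test_that("oracle equivalence holds in flag_gap delay mode too", {
  set.seed(77)
  pol <- phase_config("P2", delay_mode = "flag_gap")
  for (i in 1:60) {
    s <- random_stream(n = sample(5:30, 1))
    expect_equal(as.data.frame(detect(s, pol)[alert_cols]),
                 as.data.frame(detect_bruteforce(s, pol)[alert_cols]))
  }
})

test_that("alert counts are monotone in policy strictness", {
  set.seed(515)
  for (i in 1:40) {
    s <- random_stream(n = sample(10:50, 1))
    crit <- default_criteria("P3")
    n_by_min <- vapply(1:3, function(k) {
      nrow(detect(s, phase_config("P3", min_distinct_criteria = k,
                                  criteria = crit)))
    }, double(1))
    expect_true(all(diff(n_by_min) <= 0))
    n_by_refr <- vapply(c(0, 15, 30, 60), function(r) {
      nrow(detect(s, phase_config("P2", refractory = r, criteria = crit)))
    }, double(1))
    expect_true(all(diff(n_by_refr) <= 0))
  }
})

test_that("consecutive alerts respect the refractory per patient", {
  set.seed(616)
  for (i in 1:40) {
    s <- random_stream(n = sample(10:60, 1), n_patients = 3)
    for (r in c(15, 30)) {
      a <- detect(s, phase_config("P2", refractory = r))
      gaps <- unlist(lapply(split(a$fired_at, a$patient_id), function(ts) {
        if (length(ts) < 2) numeric(0) else diff(as.numeric(ts)) / 60
      }))
      expect_true(all(gaps >= r))
    }
  }
})

test_that("detect is deterministic and empty streams yield no alerts", {
  s <- random_stream(n = 20)
  p <- phase_config("P3")
  expect_identical(detect(s, p), detect(s, p))
  expect_equal(nrow(detect(vital_stream(), p)), 0)
  expect_equal(nrow(detect_bruteforce(vital_stream(), p)), 0)
})
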