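---
title: "Methods: trigger policies, simulator, and audit conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trigger policies, simulator, and audit conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emews)
```

## The alerting model

`emews` models an EMR-integrated maternal early-warning pipeline as four
pure stages over a timestamped vital-sign stream:

1. **Criteria.** Each sample is checked against per-parameter thresholds.
   A violation yields a *criterion flag* carrying the patient, instant,
   parameter, value, and violated rule. Oliguria is the one
   duration-qualified criterion: it flags at an instant `t` only when every
   urine-output reading in `[t − duration, t)` is below the rate threshold
   *and* at least two readings exist in that window.
2. **Trigger policy.** Flags become alerts under a `phase_config`: at each
   flag instant `t`, the engine counts *distinct parameters* with flags in
   the half-open window `(t − lookback, t]` and fires iff the count reaches
   `min_distinct_criteria` and at least `refractory` minutes have passed
   since the patient's previous alert.
3. **Acknowledgement.** Each alert receives exactly one of four nurse
   responses, or is closed as `not_acknowledged` by an explicit audit-time
   horizon operation. No timeout is modeled; none is defined for the
   workflow being emulated.
4. **Audit.** Daily counts over calendar days, mean and range, the
   five-outcome frequency table, and per-criterion attribution.

The assumptions worth stating: alerts can only be caused by an arriving
abnormal value, so evaluation is anchored at flag timestamps (nothing fires
in the interior of a quiet interval); patients are independent (no shared
ward-level suppression); and refractory state never resets, because the
data model carries no care-transition signal.

## Tunable parameters

| Parameter | Unit | Default | Why |
|---|---|---|---|
| `sbp_low` / `sbp_high` | mmHg | 90 / 160 | national maternal-safety consensus criteria |
| `dbp_high` | mmHg | 100 | same; no low bound is used clinically |
| `hr_low` / `hr_high` | beats/min | 50 / 120 | same |
| `rr_low` / `rr_high` | breaths/min | 10 / 30 | same |
| `spo2_low` | % | 95 | same; the "on room air" qualifier is dropped because oxygen-therapy context is not in the flowsheet data model |
| `temp_low` / `temp_high` | °C | 36 / 38 | fever/hypothermia screening criterion; the upper bound is inclusive (≥38) |
| `oliguria_rate` / `oliguria_duration` | mL/hr, min | 35 / 120 | sustained low output, not a single reading |
| `min_distinct_criteria` | count | P1/P2: 1, P3: 2 | phase presets of the deployed system |
| `lookback` | min | P1/P2: 0, P3: 30 | 0 means only simultaneous flags count |
| `refractory` | min | P1: 0, P2: 15, P3: 30 | inter-alert suppression |

All criteria thresholds are overridable from the YAML `criteria:` block;
only the temperature pair is a verbatim published bound, the rest follow the
cited consensus criteria because the deployed system's threshold figure is
not machine-readable.

## Numerical and boundary conventions

- **Boundary semantics.** Low bounds are strict (`value < low` flags) and
  high bounds strict (`value > high`), except temperature's inclusive upper
  bound (`≥ 38`). These are fixed, documented, and tested, to prevent
  silent off-by-one drift; exactly-at-threshold values (HR 120, SpO2 95,
  TEMP 36.0) are normal.
- **Window semantics.** `(t − lookback, t]` half-open: a flag exactly at
  the window's trailing edge belongs to the *later* window only, so no flag
  anchors two windows. With `lookback = 0` only flags at exactly `t` count.
- **Simultaneous flags** (equal timestamps, different parameters) are
  evaluated together; at most one alert fires per patient-instant, matching
  one pop-up per event. The contributing set is the most recent flag per
  distinct in-window parameter, later file order winning exact ties.
- **Percentage display.** Audit percentages are round-half-up to integers;
  a nonzero count that rounds to 0 displays `"<1"`. This reproduces every
  cell of the published five-row acknowledgement table (1368→52, 751→28,
  425→16, 86→3, 13→"<1"). Banker's rounding also matches those five cells
  but is unconventional in clinical reports.
- **Daily bucketing.** Calendar days in a configured reporting timezone
  (default UTC); partial first/last days count as full days; zero-alert
  days enter both the mean and the range. Timestamps must carry an explicit
  UTC offset at ingest precisely so this bucketing is unambiguous.
- **Degenerate inputs.** An empty flowsheet is a valid empty stream (not an
  error); an empty alert log reports 0 alerts and mean 0.0 with all-zero
  percentages; an oliguria history with fewer than two in-window readings
  never flags; out-of-plausibility values (SpO2 > 100 %, TEMP outside
  25–45 °C, negative anything) are rejected at ingest with line numbers —
  a safety system should be loud about bad input. A `skip_invalid` ingest
  mode warns and continues for retrospective batch work.

## Design choices that were genuinely open

- **The phase-2 "15-minute delay".** The deployed system's description of a
  delay "between detected abnormal vital signs" admits two readings: a
  minimum gap between abnormal *readings*, or between *alerts*. The
  parallel phase-3 wording ("a 30-minute timeframe for a subsequent alert")
  is unambiguously about alerts, so the default reads phase 2 the same way
  (inter-alert refractory). The alternative is preserved as
  `delay_mode = "flag_gap"` and tested against the brute-force oracle in
  both modes.
- **"≥2 criteria" means distinct parameters**, not two readings of one
  channel. Repeated artifacts on a single channel (movement, pushing) are
  exactly what the tightened trigger was introduced to silence; counting
  repeats would defeat it.
- **Urine output is ingested as a rate (mL/hr)**, not as voided volumes,
  because the criterion thresholds a rate and no volume-recording protocol
  is defined. The ≥2-in-window-readings requirement makes the duration
  criterion meaningless-from-one-reading impossible and suppresses the
  single-entry charting artifacts that plagued the deployed system.
- **Temperature is enabled in phase 3 only.** The published narrative says
  the criterion "was added" without stamping the phase; placing it in P3
  alongside the urine-output removal is this package's choice.
- **Refractory suppression is unconditional per patient** — it applies
  across different criteria pairs, not only identical ones.
- **Acknowledgement label wording** differs between the pop-up options
  ("MD aware, ongoing monitoring") and the audit table ("MD aware, ongoing
  treatment") in the source material; one canonical machine label
  (`md_aware_ongoing`) carries both display strings so the data model stays
  internally consistent.

## What the simulator emulates — and what it does not

`simulate_ward()` reproduces the *monitoring protocol*, not labor
physiology. Per patient it schedules: a full vitals set 30 min after
admission and 4-hourly thereafter; SBP/DBP/HR every 15 min after an
epidural (plus hourly urine-output charting, the patient being
catheterized); hourly temperature after rupture of membranes; and the full
set every 15 min for two hours after delivery. SBP/DBP/HR/SpO2 are
monitor-sourced; RR, temperature, and urine output are manual entries with
a uniform 0–10 min entry lag (whole seconds, so serialized streams
round-trip exactly), which exercises the engine's window-boundary logic.

Values are truncated-normal draws around configurable baselines (HR 85 ± 8,
SBP 118 ± 9, DBP 72 ± 7, RR 16 ± 2, SpO2 98 ± 1, TEMP 36.9 ± 0.2, urine
60 ± 15 mL/hr) — plausible stable intrapartum values shipped as
configuration, not claims about any real population. Truncation uses the
inverse-CDF construction at the hard plausibility bounds. Artifacts replace
monitor samples with probability `artifact_rate` (default 0.05, a free
parameter — no artifact frequency is published) by a uniform draw from an
extreme band (e.g. HR on [130, 180] or [25, 45], side by fair coin).
Deterioration adds linear drift to affected parameters from an onset
instant; battery-generated deteriorating patients get an epidural at
admission (15-minute HR/BP cadence is what makes a drift observable and
alertable) with HR +15 and SBP +12 units/hour from mid-labor.

Not emulated: fetal heart rate, pharmacology, realistic labor curves,
autocorrelated vital-sign noise, missing/duplicated charting, or the
antepartum period. Consequently, passing tests show the *system logic* is
correct under controlled conditions — they do not show that alert volumes
on real patients would match. The deployed system's audit magnitudes
(phase-1 ≈ 30/day falling to ≈ 7/day) are population-dependent; only the
*direction* of the phase effect is a testable property here, and the test
suite asserts exactly that.

One deliberate consequence of the cadence model: with 4-hourly routine
charting, two urine-output readings never share a 2-hour window, so
oliguria is only detectable for catheterized (epidural) patients with
hourly output — mirroring how sparse manual charting starves a duration
criterion in practice.

## Determinism and problem sizes

Every stochastic component takes an explicit integer seed and uses a
private RNG scope (the caller's `.Random.seed` is saved and restored), so
identical `(scenarios, seed)` give byte-identical streams, and the
end-to-end pipeline writes byte-identical artifact bundles under one seed —
`config.yaml` snapshots the resolved configuration, and re-running from the
snapshot reproduces every file.

The test suite exercises the engine against an independently written
quadratic brute-force oracle on 510+ random stream-policy cases, checks
policy monotonicity (raising the criteria minimum or the refractory never
adds alerts) and the refractory invariant on dozens of random streams, and
calibrates the simulator on a 30-patient, ~10,500-monitor-sample ward
(artifact fraction within 3 binomial SEs of the configured rate; drift
slope within 2 SEs of the configured value by linear fit). These sizes keep
the full suite around a minute on a laptop-class core while leaving the
binomial and regression checks well-powered.

## Known limitations

- Thresholds other than the temperature pair are consensus-criteria
  defaults, not transcriptions of the deployed system's figure.
- The audit reproduces whatever reporting period it is given; the published
  mean-alerts/day figure is not derivable from the published period and
  total, so no daily-rate value is treated as ground truth.
- The simulator's independence assumptions (no autocorrelation, no charting
  gaps) make it a verification harness, not a forecasting tool.
- Real-time operation, escalation chains, and multi-unit routing are out of
  scope; the engine is a batch function over a recorded stream.
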