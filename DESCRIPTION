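Package: emews
Title: Electronic Maternal Early Warning System Alerting and Audit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Threshold-based maternal early-warning alerting for intrapartum
    vital-sign streams. Evaluates flowsheet vitals against configurable MEWS
    abnormality criteria, converts criterion flags into alert events under
    phased trigger policies (single-criterion, time-delayed, and two-or-more
    distinct criteria within a 30-minute lookback with an inter-alert
    refractory), models the nurse acknowledgement workflow, and computes audit
    statistics (daily alert counts, acknowledgement frequency tables with
    clinical-report percentage display, per-criterion attribution). Includes a
    seeded synthetic labor-ward vital-sign simulator with protocol monitoring
    cadences, monitor artifacts, and optional deterioration episodes, plus a
    ground-truth sidecar so the whole system is exercisable without clinical
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
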