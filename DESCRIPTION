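Package: itchalert
Title: Pruritus Alert Generation and Clinic-Visit Attribution for
    Canine Activity-Monitor Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how digital pruritus alerts from wearable
    canine activity monitors relate to veterinary clinic visits. Implements
    the alerting algorithm used by collar telemetry systems (7-day rolling
    averages of daily scratching and licking, ordinal severity levels,
    day-over-day level-rise alerts with data-sufficiency rules), one-to-one
    attribution of alerts to the first clinic visit within a 28-day window,
    dermatitis subgrouping, prescription classification, and 2x2 odds-ratio
    comparison of a pre-alert versus post-alert period with log-method
    confidence intervals. Includes a synthetic-cohort generator with a
    configurable owner-response effect so the full pipeline can be run and
    validated without access to proprietary telemetry or health-record data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
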