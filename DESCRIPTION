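Package: sitless
Title: Free-Living Glucose and Posture Analysis for Sitting-Substitution
    Crossover Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the glycaemic effect of substituting
    sitting with standing and walking in free-living crossover trials.
    Reads flash glucose monitor (FGM) 15-minute epoch exports and
    activPAL posture-event streams, applies valid-day filtering, detects
    per-day waking windows, computes daily and postprandial glucose
    metrics (mean, %CV, time in range, net incremental area under the
    curve) and posture/stepping outcomes (sedentary bouts, sit-upright
    transitions, cadence-classified stepping, protocol compliance), and
    estimates adjusted regimen contrasts with linear mixed models and
    Cohen's d. Includes a calibrated synthetic-data generator for an
    N-participant two-regimen crossover so the whole pipeline can be
    exercised and validated without participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    lme4,
    lmerTest,
    lubridate,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
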