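Package: mwlmetrics
Title: Multimodal Mental-Workload Metrics for Simulated Assembly Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies mental workload from cardiac and oculomotor signals
    recorded during manual-assembly sessions. Provides time-domain heart rate
    variability indicators (RMSSD, relative RR intervals, rrHRV), sliding-window
    heart rate, pupil-diameter preprocessing (outlier removal, gap interpolation,
    binocular averaging), fixation and saccade summaries, area-of-interest dwell
    and revisit analysis, SD-threshold over/underload time-in-state
    quantification, and mixed-design (split-plot) repeated-measures ANOVA with
    partial eta squared. A synthetic-cohort simulator generates complete
    sessions (schedules, RR series, ECG traces, pupil traces, gaze events,
    performance records) with the statistical structure the analysis assumes,
    so the full pipeline is testable without participant data.
License: MIT
Encoding: UTF-8
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
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
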