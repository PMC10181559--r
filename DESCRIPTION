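Package: prvkit
Title: Pulse Rate Variability from Low-Cost Photoplethysmography
Version: 0.1.0
Authors@R:
    person("prvkit", "developers", email = "prvkit@example.org", role = c("aut", "cre"))
Description: Toolkit for extracting ultra-short-term time-domain pulse rate
    variability (PRV) from low-sample-rate photoplethysmography (PPG)
    recordings, and for evaluating its agreement against ECG-derived heart
    rate variability (HRV). Includes a ground-truthed synthetic PPG
    generator with respiratory sinus arrhythmia and sample dropout, a
    conditioning chain (moving average, airPLS baseline correction,
    Butterworth low-pass, second derivative), a windowed decision rule for
    beat detection on the acceleration plethysmogram (APG), SDNN/RMSSD/HR
    indicators with a data-loss statistic, and a device-agreement workflow
    (difference factors, percentage bias, Bland-Altman, normality-gated
    paired tests, Levene-gated two-way ANOVA or Scheirer-Ray-Hare with
    Dunn/Tukey post hocs, linear regression).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
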