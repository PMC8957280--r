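Package: pulseline
Title: Heart Rate and Heart Rate Variability Extraction from Cardiac Waveforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Extracts heart rate and time-domain heart rate variability from
    single-channel cardiac waveforms (ECG, finger or wrist photoplethysmography).
    Provides preprocessing (cubic-spline upsampling, zero-phase high-pass
    Butterworth filtering, Savitzky-Golay smoothing), sliding-window peak
    detection with optional k-means discrimination of ECG R waves from P and T
    waves, per-window BPM and RMSSD/SDNN/SDSD/PNN20/PNN50/HF metrics, and an
    automated battery of biological and statistical (median-absolute-deviation)
    outlier screens producing parallel cleaned and uncleaned time series. A
    labelled synthetic PPG/ECG generator plus validation statistics (intraclass
    correlation, RMSE, Cohen's d, paired-t power analysis, triaxial jerk
    magnitude) support parameter-recovery and simulated-experiment studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    tibble,
    ggplot2,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
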