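Package: stopsignal
Title: Stop-Signal Task Simulation, SSRT Estimation, Inhibition ERPs and
    Random-Effects Bayesian Model Selection
Version: 0.3.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to quantify motor inhibition in the stop-signal task and
    its modulation by subthalamic deep brain stimulation. Simulates the
    horse-race model with an adaptive +/-50 ms stop-signal-delay staircase
    (ex-Gaussian Go process, independent Stop process, trigger failures),
    estimates the stop-signal reaction time (SSRT) by the integration
    method, synthesizes multichannel EEG epochs with known ground-truth
    inhibition components, isolates inhibition event-related potentials by
    Go-process correction of successful and unsuccessful stop trials,
    computes global field power and windowed peak measures, runs paired
    within-subject statistics, and performs random-effects Bayesian model
    selection, family inference and Bayesian model averaging over a
    cortico-basal-ganglia effective-connectivity model space.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    signal,
    yaml,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
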