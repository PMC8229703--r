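Package: glyjump
Title: Jump Neural Network Forecasting of Continuous Glucose Monitoring Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Short-horizon blood-glucose forecasting for continuous glucose
    monitoring (CGM) traces with a jump neural network: a single-hidden-layer
    feed-forward regressor whose inputs are also wired directly to the output
    neuron, so the prediction is the sum of a linear and a nonlinear term.
    Provides CGM preprocessing (minute gridding, gap handling, the
    continuous-24-hour-day inclusion rule), supervised window construction at
    a configurable prediction horizon, three per-patient training protocols
    (offline; online with sliding 24-hour retraining; online with a
    penalty-weighted squared-error loss), physical-activity-stratified RMSE
    evaluation, and a synthetic CGM generator with meals, circadian rhythm,
    exercise effects, autocorrelated sensor noise and dropouts so the whole
    pipeline is testable without patient data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
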