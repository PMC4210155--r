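Package: reflexgait
Title: Reflexive Gait Control from Heel-Contact to Muscle-Activation Transfer Functions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies linear transfer functions from foot-contact (force
    sensing resistor) signals to leg-muscle EMG envelopes with least-mean-squares
    adaptive filtering, reduces them to critically damped second-order
    muscle-twitch activation curves, and deploys them in a purely reflexive
    (sensor-triggered, CPG-free) walking controller exercised on a surrogate
    planar biped. Includes a synthetic gait-recording generator with known
    ground-truth kernels, EMG linear-envelope conditioning, heel-strike
    detection and event-related averaging, transfer-function feature
    extraction, curve fitting, gait metrics and limit-cycle diagnostics, and
    an end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    minpack.lm,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
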