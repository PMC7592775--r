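Package: cvpulse
Title: Non-Invasive Central Venous Pressure Estimation from the Jugular Venous Pulse
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates mean central venous pressure (CVP) non-invasively from
    ultrasound-derived internal jugular vein cross-sectional area (IJV-CSA)
    pulse traces. Implements the lagged-autocorrelation feature methodology:
    zero-phase removal of non-cardiac (respiratory) frequency content,
    ECG-based synchronization of paired traces, extraction of autocorrelation
    r-values on a fixed lag grid, exhaustive minimum-AIC best-subset linear
    model selection with k-fold cross-validation, prediction of mean CVP with
    either refitted or published fixed coefficients, and three-category
    clinical classification (low/normal/high CVP) with sensitivity, accuracy
    and Cohen's kappa. A synthetic-cohort waveform generator with known ground
    truth supports end-to-end validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
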