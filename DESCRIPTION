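Package: thermovine
Title: On-the-Go Thermal Imaging Pipeline for Grapevine Water Status
Version: 0.1.0
Authors@R: person("thermovine", "maintainers", email = "maintainers@thermovine.org", role = c("aut", "cre"))
Description: Estimates grapevine midday stem water potential from vehicle-mounted
    thermal camera recordings. Provides a synthetic vineyard campaign generator
    (weather, wet/dry reference temperatures, canopy thermal frames, ground-truth
    stem water potential), acquisition-geometry arithmetic (scene coverage, frame
    counts, non-overlap subsampling, middle-frame selection), per-frame feature
    extraction with the crop water stress index (CWSI) and the conductance index
    (Ig), a from-scratch rotation-forest regressor over reduced-error-pruning
    trees, and a calibration / 10-fold cross-validation / external-prediction
    evaluation protocol with a slope-equality test between canopy-side models.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
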