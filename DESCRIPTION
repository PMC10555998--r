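Package: tipstress
Title: Tipping-Point Detection and Stressor-Interaction Classification
    Along Environmental Gradients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects ecological tipping points along a stressor gradient with
    broken-line (segmented) regression and a Davies-type test for the
    existence of a breakpoint, corroborates them with early-warning variance
    profiles and Hartigan's dip test for multimodality, and classifies
    multi-stressor interactions (synergy, additivity, antagonistic buffering,
    suppression) with a rescaled Bliss-independence deviation-from-additivity
    metric and a multiplicative null model. Ships a synthetic-data generator
    that emulates a full-factorial mesocosm mortality experiment (nutrient
    enrichment crossed with salinity intrusion) with known piecewise-linear
    truth, so the whole pipeline runs and is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    lme4,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
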