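Package: rumeval
Title: Evaluation of Rumen Intake and Methane Prediction Models Against
    Observed Data
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for assessing the accuracy and precision of mechanistic
    predictions of dry matter intake and enteric methane emission against
    paired animal observations. Implements the mean simulated-to-observed
    ratio, zero-intercept and moment-based regression slopes, mean bias,
    model efficiency, the mean square prediction error with its
    bias/slope/random partition, and Lin's concordance correlation
    coefficient with its accuracy and precision components. Includes a
    diet-group (Leucaena) subset evaluation pipeline, a pluggable predictor
    interface with a stoichiometric stub model, a one-at-a-time
    forage-quality sensitivity analysis with principal component summary,
    and a synthetic paired-data generator for testing the full pipeline.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
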