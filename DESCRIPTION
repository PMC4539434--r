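Package: pdaseq
Title: Dynamic ODE Modeling of Per-Base RNA-seq Coverage Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models per-base RNA-seq read-coverage profiles of a gene as
    solutions of a second-order ordinary differential equation with
    location-varying coefficient functions, estimated by principal
    differential analysis (alternating penalized basis smoothing with an
    ODE-defined roughness penalty and closed-form operator-coefficient
    updates).  The fitted operator supports curve prediction through
    two-point boundary value problems with cross-validated prediction
    error, functional principal component feature extraction for
    classification (L1-penalized logistic regression) and hierarchical
    clustering, and unit-step response analysis with a Hotelling T-squared
    group-difference test.  Includes a synthetic-data generator matching
    the model's assumed data-generating process and a command-line
    interface for the main workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
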