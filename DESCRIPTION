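Package: bwestim
Title: Body-Weight Estimation from Biometric Measurements by Metaheuristic
    Polynomial Fitting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates livestock body weight from seven depth-sensor biometric
    measurements with an adjustable-degree multivariate polynomial whose
    coefficients and integer exponents are fitted by a genetic algorithm with
    elitism or by cuckoo search with Levy flights, under a shared
    fitness-evaluation budget that makes the two optimizers directly
    comparable.  Includes the depth-image measurement chain (Z-threshold
    segmentation, metric back-projection to a 1 cm/pixel planar histogram,
    landmark distance measurement) validated on synthetic ellipsoid phantoms,
    a synthetic-cohort generator with correlated allometric traits and
    sensor-noise channels, classical girth-and-length baseline formulas and
    growth curves, and a command-line interface for simulation, fitting,
    matched-budget comparison and repeated-run validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
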