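Package: lacqa
Title: Field-Size Quality Assurance for Variable-Aperture Collimators via
    Dose-Area-Product Measurements
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements a large-area parallel-plate ionization chamber (LAC)
    method for field-size quality assurance of a variable circular-aperture
    radiotherapy collimator. Provides a parametric beam model (off-center
    ratios, output factors, geometric projection, deliberate detuning), a
    dose-area-product engine based on deterministic quadrature over the
    chamber's sensitive area (aligned and misaligned), the QA statistics of
    the method (the theta quotient, percentage deviations, tolerance limits
    derived by calculation and by measurement, percent-to-millimetre
    conversion, characterization fits, an error budget), a synthetic
    measurement-session generator with the noise structure of repeated
    100-MU exposures, and readers/writers plus a command-line interface for
    sessions, baselines, limits and QA reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
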