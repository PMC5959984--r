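Package: idpsrs
Title: Isotoxic Dose Prescription Modelling for Stereotactic Radiosurgery
    of Brain Metastases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models isotoxic dose prescription (IDP) for stereotactic
    radiosurgery (SRS) of brain metastases. Provides spherical target
    geometry with PTV-size-based prescription protocols, a radially
    symmetric power-law dose-falloff surrogate for VMAT plans calibrated
    to RTOG conformity and Paddick gradient indices, cumulative
    dose-volume histogram construction and renormalisation, linear-
    quadratic conversion of normal-tissue dose-volume constraints between
    fractionation schemes, a logistic tumor control probability model,
    a synthetic cohort emulating clinically realistic (non-spherical)
    plans, and a study pipeline running the full factorial sweep over
    target size, setup margin, beam arrangement and fractionation with
    exponential-decay curve fitting and fit comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    MASS,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
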