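Package: dosevc
Title: Dose-Varying Coefficient Modelling of Drug Response with Two-Stage
    Gene Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Functional (dose-varying coefficient) regression for
    transcriptome-wide association of gene expression with anti-cancer drug
    response measured over dilution series. Normalizes raw viability assays,
    expands covariate effects in a B-spline basis over the dose fraction,
    estimates dose-varying variance and a working within-unit correlation to
    form weighted least-squares objectives, screens genes by weighted
    marginal utilities, selects genes with a group-SCAD penalty tuned by
    cross-validation, and summarizes selected effects (coefficient-curve
    areas, bootstrap uncertainty, monotonicity, predictive accuracy, sigmoid
    IC50). Includes a synthetic dose-response panel generator with known
    truth and a Monte Carlo harness for selection-performance studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    splines,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
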