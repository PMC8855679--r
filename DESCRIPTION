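Package: assayrsm
Title: Response-Surface Optimization and Quantification for Colorimetric
    Carbohydrate Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for optimizing plate-based colorimetric assays by response
    surface methodology and for quantifying tissue glycogen with the
    phenol-sulfuric acid method. Generates rotatable central composite
    designs with coded reagent volumes, fits full-quadratic response
    surfaces by ordinary least squares with hierarchy-preserving term
    reduction and small-sample AICc comparison, ranks candidate assay
    conditions by a worst-case error-propagation (total differential)
    objective under volume constraints, fits and quality-controls standard
    curves (saturation capping, robust FDR-based outlier flagging, blank
    correction, intra-assay coefficients of variation), converts curve
    readouts into tissue glycogen content with glucose/glycogen
    stoichiometry, and simulates every data type the pipeline consumes so
    the full workflow runs and is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
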