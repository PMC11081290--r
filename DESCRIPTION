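Package: rheodsd
Title: Definitive Screening and Rheological Quality-by-Design for Semisolid Formulations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for quality-by-design optimisation of semisolid (ointment)
    preparation processes from rheological responses. Builds definitive
    screening designs from conference matrices, extracts yield stress,
    power-law flow parameters and storage modulus from rheometer curves,
    fits coded second-order response-surface models by bidirectional
    stepwise selection, estimates defect rates against specification
    windows by Monte Carlo simulation with radial stratification, carves
    an axis-aligned design space with a prior-weighted classification
    tree, and refines the operating point with a Gaussian-process
    surrogate over the log10 defect rate. Includes a synthetic-data
    generator producing rheometer curves and design-of-experiments
    response tables with known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    lhs
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
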