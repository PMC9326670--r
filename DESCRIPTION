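Package: matrixbank
Title: Rule-Based Figural Matrix Item Banking with 2PL Calibration and
    Anchor Equating
Version: 0.1.0
Authors@R:
    person("Matrixbank", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for building and evaluating banks of construction-based
    figural matrix reasoning items. Generates 3x3 matrix items from six set-
    and transformation-based construction rules with a verified unique
    solution, assembles anchor-linked multi-form item banks and renders them
    to SVG, simulates dichotomous responses under the two-parameter logistic
    (2PL) item response model, calibrates forms by marginal maximum
    likelihood (EM over fixed quadrature), computes infit/outfit misfit
    diagnostics, links separately calibrated forms through common anchor
    items (mean-sigma / mean-mean), and produces the classical test theory
    and rule-based difficulty-regression report for the assembled bank.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
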