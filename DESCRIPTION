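Package: dlrobust
Title: Robustness of the Dorsal Morphogen Gradient to Maternal Dosage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse the robustness of the Dorsal (Dl) nuclear
    gradient that patterns the dorsal-ventral axis of the early Drosophila
    embryo with respect to maternal dl dosage. Implements an empirical
    dosage-scaling gradient model with analytic dosage-sensitivity
    coefficients, a compartmental reaction-diffusion model of Dl/Cactus/Toll
    dynamics over nuclear cycle 14, threshold-based prediction of
    gene-expression borders scored against measured 1x/2x/4x border positions,
    a random-parameter robustness screen with ensemble analytics, profile
    quantification (Gaussian gradient fits, canonical gene-expression
    templates, half-max borders), dosage statistics (log-log sensitivity
    slopes, weighted qPCR summaries, bootstrap amplitude ratios), and a
    synthetic-data generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    knitr
Config/testthat/edition: 3
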