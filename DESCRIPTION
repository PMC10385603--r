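Package: cudosim
Title: Preclinical Dosimetry and Efficacy Analytics for Copper-64
    Antibody Radioimmunotherapy
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for preclinical copper-64 theranostic studies
    in mouse tumour models: ex vivo biodistribution expressed as percent
    injected dose per gram with tail-remainder and physical-decay
    corrections, exponential and plateau-uptake time-activity curve fitting
    with analytic integration to time-integrated (cumulated) activity, MIRD
    mean absorbed doses from unit-density sphere self-dose S-values and a
    local-deposition blood model, saturation-binding and immunoreactivity
    assay arithmetic, tumour growth and Kaplan-Meier survival analytics, and
    a seeded synthetic-cohort generator reproducing the statistical
    structure of such studies for end-to-end testing.
License: GPL-3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    survival,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
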