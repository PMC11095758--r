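Package: pidquant
Title: Whole-Core HER2 Quantification from Phosphor-Integrated-Dot Fluorescence Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies HER2 expression per tissue-microarray core from
    phosphor-integrated-dot (PID) fluorescence whole-slide rasters: tiles the
    pathologist-annotated invasive-cancer region into 12-micrometre squares,
    integrates fluorescence per tile, and summarises each core as the mean of
    the top 10 percent of tile integrals (the PID value). Derives data-driven
    cut points from per-class PID-value minima to assign tentative IHC
    categories (0/1+/2+/3+), flags candidate HER2 "ultra-low" cores against a
    negative-control intensity floor, and reports concordance with pathologist
    DAB scores (regression R-squared, contingency tables with row percentages,
    variance-test-gated two-sample comparisons, replicate reproducibility).
    Includes a seeded synthetic TMA-core generator (Gaussian point-spread spot
    model over a connected invasive mask) so the whole pipeline is testable
    without slide images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    withr
Suggests:
    readxl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
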