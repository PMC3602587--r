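Package: effectorscreen
Title: Companion-Effector Combination Screening Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for high-throughput combination screens that
    use a low-potency companion effector (e.g. a nutraceutical such as
    resveratrol) to reveal library compounds whose potency it enhances
    (agonists) or suppresses (antagonists). Provides 384-well plate data
    structures and delimited-text I/O, control-run quality control (Z'-factor,
    signal-to-noise, CV), growth-kinetics linearity assessment, a
    nephelometry-based aqueous solubility limit rule, percent-inhibition
    normalization, duplicate-screen concordance, dual-condition hit selection
    with cross-cell-line refinement, censored four-parameter logistic
    dose-response fitting with partial-curve and censoring rules, fold-shift
    algebra over censored IC50 values, agonist/antagonist confirmation and
    cell-line panel profiling, nuclei-count image analysis on synthetic
    micrographs, and seeded generators of synthetic plate data with planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    EBImage,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
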