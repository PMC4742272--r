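Package: chromoscore
Title: Cardiomyocyte Nuclear Chromatin Morphometry from Electron Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-step morphometric analysis of cardiomyocyte nuclear chromatin
    in 8-bit transmission electron micrographs: Z-disk-anchored grayscale
    calibration, extraction of the perinuclear condensed-chromatin ring and a
    topological continuity verdict (Group A vs Group N), and the nucleoplasmic
    (Nuc-CS) and perinuclear (Per-CS) chromatin scores for continuous-ring
    nuclei. Includes percent-fibrosis quantitation from Masson-trichrome RGB
    scans, the cohort statistics layer (group comparisons, 2x2 outcome tables,
    ROC/AUC with DeLong intervals, interobserver ICC), and a seeded synthetic
    generator of EM-like nuclei, cohorts and trichrome slides with analytic
    ground truth so every pipeline stage is testable without real micrographs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    png,
    tiff,
    pROC,
    jsonlite,
    yaml,
    stats,
    grDevices,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
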