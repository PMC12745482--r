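Package: tibiaqct
Title: Quantitative CT Bone Densitometry and Method Agreement for Laying-Hen Tibiae
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to compare computed-tomography based measurements of tibial
    bone mineral density (BMD) in laying hens. Implements hydroxyapatite
    phantom calibration of Hounsfield units to mgHA/cm3, a quadrant-based
    cortical region-of-interest method (M1), a whole-bone seeded
    region-growing method (M2), the full method-agreement statistics suite
    (Pearson, Bland-Altman with proportional-bias regression, Lin's
    concordance correlation with bias-correction factor, Deming regression
    with jackknife confidence intervals), and a regression screen of bone and
    eggshell traits against BMD with signed coefficients of determination.
    Includes a synthetic-CT cohort generator with known ground-truth density
    so the whole pipeline is testable end to end without scanner data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    EBImage
Config/testthat/edition: 3
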