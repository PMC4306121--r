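Package: plaqueMech
Title: Hyperelastic Material Models and Revascularisation Stress Analysis
    for Atherosclerotic Plaque
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Constructs Yeoh hyperelastic material models for atherosclerotic
    plaque tissue from planar-shear stress-stretch data, classifies plaques by
    calcification grade from ATR-FTIR absorbance spectra via the
    calcification-to-lipid peak-area ratio, and solves the displacement-driven
    revascularisation of an idealised concentric femoral stenosis under
    plane-strain incompressibility. Quantifies how the choice of plaque
    material model (femoral- versus aortic-derived coefficients) changes the
    maximum principal stress in the plaque and the predicted tissue failure,
    including the fold change in stress at a fixed depth from the lumen.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
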