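Package: magdensity
Title: Quantitative MRI Breast Density from Multi-Echo Fat-Water Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for MRI-based quantitative
    breast density. Generates synthetic multi-echo gradient-echo breast
    acquisitions for several scanner configurations, reconstructs water,
    fat and fat-fraction maps by iterative least-squares fat-water
    decomposition (IDEAL), converts fat fractions into bias-corrected
    volumetric water fractions (FraWater) using reference-region
    correction factors, summarises per-breast density (MagDensity), and
    quantifies and removes cross-scanner disagreement with paired
    statistics, Bland-Altman analysis and leave-one-out linear
    calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
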