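Package: oralscreen
Title: Dual-Modality Oral Cancer Screening Image Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis stack for smartphone-based dual-modality (white-light +
    autofluorescence) oral cancer screening. Provides autofluorescence
    lesion-highlighting maps (green mean-subtraction, red/green ratio) and the
    on-device suspicious/not-suspicious call, camera-RGB to CIEXYZ color-matrix
    fitting from a 24-patch checker, optical and illumination quality control
    (even-asphere sag, USAF target frequencies, PSF- and slanted-edge MTF,
    coefficient-of-variation uniformity), screening-study evaluation statistics
    (confusion metrics, ROC/AUC, stratified cross-validation with dihedral
    augmentation), seeded synthetic phantom generators with ground truth, and a
    case-store workflow with JSON summary reports.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    png,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
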