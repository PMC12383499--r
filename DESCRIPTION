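Package: hepatrack
Title: Longitudinal 3D Tracking of Liver Metastases from Segmentation Masks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tracks individual liver metastases between a baseline and a
    follow-up examination using only binary segmentation masks (NIfTI).
    Lesions are isolated by 3D connected-component labelling, the two
    timepoints are aligned by a rigid registration of the liver masks,
    correspondences are established from centroid distance and Dice
    overlap, and per-lesion differential growth (volume and largest axial
    diameter, absolute and relative) is quantified and categorised with
    RECIST 1.1-adapted thresholds (progressive, stable, regressive, new,
    merged, too small to measure). Results are assembled into ordered
    decision-support reports, category-coded label volumes, and plots.
    A phantom generator produces paired masks with scripted growth,
    motion, appearance, disappearance and merge events plus ground truth,
    so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    tibble,
    dplyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    yaml,
    ggplot2,
    generics,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
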