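Package: ctpaindices
Title: Right-Heart Dysfunction Indices from CTPA Segmentation Masks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes three axial CT indices of right-heart strain from labeled
    CTPA (computed tomography pulmonary angiography) segmentation volumes: the
    right-to-left ventricular diameter ratio (RV/LV), the pulmonary artery to
    ascending aorta diameter ratio (PA/AA), and the ventricular septal angle
    (SA). Diameters are maximal horizontal (x-parallel) chords on
    automatically selected axial slices; the septal angle is measured against
    a spine-parallel reference axis derived from the lung mask. Includes
    agreement statistics used to validate automated against manual
    measurements (Dice coefficient, one-way random-effects intraclass
    correlation with exact-F confidence intervals, tolerance-based accuracy
    with bootstrap standard errors, Bland-Altman limits of agreement), a
    parametric axial chest phantom generator with closed-form ground-truth
    indices for end-to-end validation, a small trainable U-Net segmentation
    stage for toy-scale experiments, and command-line entry points.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
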