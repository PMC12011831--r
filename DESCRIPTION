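Package: octavasc
Title: Quantification of Retinal Microvasculature from En-Face OCTA with
    Cohort-Level Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying the retinal microvasculature on en-face
    optical coherence tomography angiography (OCTA) images and relating the
    resulting vessel metrics to clinical observations in diabetic
    retinopathy cohorts. Provides annulus/quadrant/sector region-of-interest
    geometry for disc and macula scans, Hessian-based vessel enhancement,
    binarization, large-vessel removal, topology-preserving skeletonization
    and the six standard vessel parameters (area density, skeleton density,
    diameter index, perimeter index, complexity index, flux); Snellen to
    LogMAR conversion and visual-acuity stability classification;
    control-standardized blood-panel z-scores; nonparametric group
    comparisons and OCT-by-OCTA Spearman correlation matrices with
    Bonferroni correction; and a synthetic-data module generating vascular
    phantoms with ground-truth masks and grade-conditional clinical cohorts
    so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    tiff,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
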