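Package: myoUS
Title: Semi-Automated Myositis Classification from Muscle Ultrasound
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of B-mode muscle ultrasound for inflammatory
    myopathy (myositis) classification. Extracts a 22-element per-image feature
    vector from clinician-delineated muscle and subcutaneous fat regions --
    echointensity statistics, Nakagami speckle-distribution parameters and 13
    Haralick gray-level co-occurrence texture features -- and classifies images
    with a random-forest ensemble, evaluated by muscle-entity-grouped five-fold
    cross-validation reporting accuracy, sensitivity, specificity, predictive
    values, Cohen's kappa and likelihood ratios. Includes a Nakagami speckle
    phantom generator that emulates the acquisition protocol (seven muscle
    groups, bilateral, up to three views, a subcutaneous fat band over muscle)
    so the full pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    png,
    tiff,
    RNifti,
    randomForest,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
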