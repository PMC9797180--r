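Package: radUnique
Title: Radiomic Feature Uniqueness Screening by ROI Translocation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Assesses whether radiomic features extracted from a tumor region
    of interest (ROI) are unique to the underlying structure. The tumor ROI is
    rigidly translocated, shape-preserved, into adipose, heart, lung and
    muscle regions of the same CT volume; 123 radiomic features across seven
    categories (intensity statistics, intensity histogram, Gaussian histogram
    fit, 2D/3D gray-level co-occurrence, gray-level run length, 2D/3D
    neighborhood gray-tone difference, gradient orientation histogram) are
    extracted from each placement. Per-patient coefficients of variation
    across the five placements and Lin's concordance correlation coefficients
    between tumor and each tissue are aggregated across patients, tissue
    pairs and cohorts to classify every feature as unique or nonunique.
    Includes a deterministic synthetic CT phantom generator with five labeled
    tissue classes so the full pipeline runs without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    mclust,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
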