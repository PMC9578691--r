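Package: gastruquant
Title: Morphometry, Axial Expression Profiling and Rule-Based Cell
    Classification for Gastruloid Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantification toolkit for gastruloid experiments: segmentation
    and morphometric analysis of 2D fluorescence images (area, Feret
    diameters, elongation index, circularity-filtered nucleus
    quantification), anterior-posterior reporter intensity profiling with
    1%-length binning, DAPI normalization and k-means clustering of binned
    profiles, and rule-based single-cell operations (QC and CPM filtering,
    Hox/brain/spinal-cord categorization, dorsal-ventral module assignment,
    differential cell-type abundance, pseudo-bulk means). Ships seeded
    synthetic-data generators for gastruloid-like images and
    marker-structured count matrices with ground truth, so every stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    Matrix,
    jsonlite,
    yaml,
    tiff,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
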