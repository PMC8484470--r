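Package: wbcseg
Title: Nucleus Segmentation and Classification of White Blood Cells in
    Stained Smear Crops
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Segments the nucleus of a white blood cell in a single-cell
    crop of a stained peripheral-blood smear using a colour-balanced
    CMYK/HLS soft map thresholded by Otsu's method, derives a cytoplasm
    proxy from the convex hull of the nucleus, extracts a fixed
    51-dimensional shape and colour-ratio feature vector, and classifies
    the five leukocyte types with a class-weighted support vector
    machine. Includes geometric training-set augmentation, segmentation
    and classification metrics, and a parametric generator of
    Giemsa-like synthetic crops with exact ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    EBImage,
    e1071,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
biocViews: CellBiology, Classification, Segmentation
RoxygenNote: 7.3.3
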