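Package: algascope
Title: Automated Recognition and Classification of Freshwater Algae Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for detecting and classifying freshwater
    algae genera (Navicula, Scenedesmus, Microcystis, Oscillatoria,
    Chroococcus) in light micrographs. Implements histogram-equalization
    preprocessing, Canny edge based segmentation with morphological cleanup
    and watershed separation of touching objects, a 21-dimensional shape and
    Fourier-spectrum texture feature extractor with PCA compression, and a
    21-8-5 hyperbolic-tangent multilayer perceptron trained by momentum
    backpropagation with cross-validated early stopping. Includes a seeded
    synthetic micrograph generator with ground-truth masks so the full
    pipeline can be exercised and benchmarked without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    png,
    tiff,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
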