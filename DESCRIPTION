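Package: netrsa
Title: Network-Level Representational Similarity Analysis of Person-Knowledge fMRI Responses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for network-level representational similarity analysis
    (NetRSA) of region-of-interest fMRI responses. Includes a seeded synthetic
    data generator with planted task and regional structure, a minimal
    block-design general linear model, spherical ROI extraction in MNI space
    with control-condition baseline subtraction, per-subject correlation-distance
    matrices over tasks and regions with Ward hierarchical clustering and
    classical multidimensional scaling, and the inferential machinery for
    comparing observed similarity structures against theoretical and empirical
    models (per-subject model fits, one-sample and paired t-tests, Bonferroni
    correction, minimal-detectable-effect power computation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    ape,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
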