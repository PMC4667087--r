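Package: wmlstager
Title: Staging of White Matter Lesions from Multispectral MRI and Their
    Longitudinal Cognitive Correlates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Segments multispectral brain MRI (FLAIR, T2, MT/T1-like
    channels) into tissue probability maps with a self-supervised
    discriminative clustering method, stages white-matter lesion voxels
    into small, intermediate and fully developed partial-volume
    categories, and relates the staged lesion volumes to longitudinal
    cognitive decline with REML linear mixed models using an
    unstructured within-subject covariance. Includes a synthetic
    longitudinal phantom generator with known tissue fractions and a
    matched cognition simulator, so the whole pipeline is testable
    end-to-end without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    igraph,
    jsonlite,
    pracma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    nlme,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
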