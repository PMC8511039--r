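Package: pyramidwsi
Title: Pyramidal Multi-Scale CNN Classification of Kidney Histology Slides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for classifying kidney histology slide images into
    four tissue classes (fat, renal parenchyma, clear cell papillary renal
    cell carcinoma, clear cell renal cell carcinoma) plus background.  Slides
    are decomposed into overlapping patches at three spatial scales (250, 350
    and 450 pixels), enhanced by contrast limited adaptive histogram
    equalization and edge sharpening, and classified by three lightweight
    convolutional networks sharing one architecture.  Patch labels are
    aggregated to a pixel-level classification map by per-pixel majority
    voting, the three scale-specific maps are fused, and the fused map is
    smoothed with a generalized Gauss-Markov random field prior.  A synthetic
    slide generator provides texture-distinct fixtures so the entire pipeline
    runs without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    png,
    tiff,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
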