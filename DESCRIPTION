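Package: dtctrack
Title: Detect, Track and Colocalize: Spot-Based Organelle Association
    Analysis for Two-Channel Live-Cell Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of diffraction-limited fluorescent spots
    in two-channel 2D time-lapse microscopy. Provides threshold-based spot
    detection with a circularity filter, per-dot and plasma-membrane-band
    intensity quantification, object-based (centroid-distance)
    colocalization against the optical resolution limit, single-frame
    association calling within a pixel-distance window, nearest-neighbour
    particle tracking under a maximum-displacement constraint with
    per-track association profiles and run-duration statistics
    ("Detect, Track and Colocalize"), a synthetic two-channel movie
    simulator with full ground truth, and nonparametric group comparisons
    (Wilcoxon rank-sum, Kruskal-Wallis, Dwass-Steel-Critchlow-Fligner with
    Monte-Carlo permutation p-values).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
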