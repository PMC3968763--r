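Package: phogaes
Title: PHOG Image Statistics, Rater Clustering, and Perceptual Contrast for
    Abstract-Art Beauty Ratings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes statistical image properties of paintings and other
    raster images via the pyramid of histograms of oriented gradients (PHOG):
    self-similarity through the histogram intersection kernel, complexity,
    anisotropy, a Birkhoff-like order/complexity ratio, plus per-channel color
    statistics in HSV, RGB, and CIE Lab space.  Provides the companion
    behavioral pipeline: k-means clustering of raters by their beauty-rating
    profiles, selection of cluster-specific adaptor and evaluation image sets,
    the perceptual-contrast (adaptation aftereffect) analysis with paired
    tests, and association layers (Spearman tables, standardized multivariate
    regression, linear mixed models with cluster-by-property interactions).
    A synthetic-data module generates images with controlled gradient and
    color structure and rater populations with latent preference clusters, so
    the whole pipeline is testable without copyrighted artworks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    generics,
    ggplot2,
    grDevices,
    lme4,
    lmerTest,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
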