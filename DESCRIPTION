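Package: grainray
Title: Non-Destructive Rice Grain Trait Inference from 2D X-Ray Radiographs
Version: 0.1.0
Authors@R:
    person("grainray", "developers", email = "grainray@example.org",
           role = c("aut", "cre"))
Description: Tools to estimate physical quality traits of paddy rice from a
    single 2D X-ray radiograph of a gridded sample holder. The pipeline
    normalizes the radiograph by the Beer-Lambert transform, segments
    individual grains with a dual (foreground/background plus
    distance-transform instance) watershed, extracts eight blob descriptors
    per grain, embeds them by z-scoring and a three-component PCA, and
    predicts three traits: chaffiness by a Mahalanobis-distance threshold,
    chalky-kernel status by a linear support-vector hyperplane after a
    "virtual de-husking" feature-space shift, and head-rice-recovery class
    by a five-class maximum-probability rule. An analytic ellipsoid phantom
    simulator with exact ground truth makes every stage testable without
    scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    data.table,
    digest,
    png,
    stats,
    utils,
    grDevices,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
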