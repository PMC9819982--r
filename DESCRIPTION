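Package: smoglink
Title: Two-Regime Spatial Durbin Models and Haze-Linkage Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for diagnosing strategic interaction in regional
    environmental regulation. Builds gravity-model haze-linkage networks
    between regions, tests spatial autocorrelation with global and local
    Moran's I (normal and permutation inference), and estimates a
    two-regime spatial Durbin panel model with two-way fixed effects by
    maximum likelihood, in which regime-specific spatial-reaction
    coefficients distinguish race-to-the-bottom from race-to-the-top
    competition among regional governments. Includes a model-selection
    battery (LM, robust LM, LR, Wald, Hausman tests), a synthetic panel
    generator that simulates from the two-regime data-generating process
    with a self-consistent regime indicator, and an end-to-end pipeline
    with a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    igraph,
    MASS
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
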