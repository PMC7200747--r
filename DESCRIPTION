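Package: patsep
Title: Lifespan Analysis of Mnemonic Discrimination and Hippocampal
    Subfield Structure and Function
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scoring, simulation and statistical modelling tools for
    behavioural pattern-separation studies across the adult lifespan.
    Scores mnemonic similarity task sessions into the Lure Discrimination
    Index and Corrected Recognition Score; generates synthetic lifespan
    cohorts with configurable age-varying structure-function coupling
    between hippocampal subfield volumes, subfield activation and task
    performance; fits generalized additive models with smooth-versus-linear
    model selection and tensor-product age interactions; and locates
    regions of significance (floodlight analysis) for quartile-contrast
    difference curves along the age axis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ggplot2,
    jsonlite,
    mgcv,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
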