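Package: yieldstab
Title: Yield Stability and Source-Sink Analysis for Multi-Environment Wheat Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing genotype-by-environment-by-management
    interactions in multi-environment cereal trials. Implements dual-perspective
    trait stability indices (genotypic superiority measure and Wricke's
    ecovalence), thermal-time phenology with logistic canopy-senescence fitting
    and green canopy duration, partitioning of spike dry matter, nitrogen and
    water-soluble carbohydrates at maturity into pre-anthesis reserves, straw
    remobilization and post-anthesis assimilation, split-split-split-plot
    analysis of variance with expected-mean-square based F tests and compact
    letter displays, scaled principal-component phenotypic spaces, and a
    ground-truth trial simulator for end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
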