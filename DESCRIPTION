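Package: ancestra
Title: Ancestry-Component Covariance Analysis of Complex Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the relative genetic similarity (covA) of
    present-day individuals to the ancestral components of an admixed
    population (e.g. Western Hunter-Gatherer, Early European Farmer and
    Steppe Bronze Age ancestries in Europe), and to test trait-ancestry
    associations with covariate-adjusted linear, logistic and ordinal
    models, including a confounder-robust within-sibship design. Includes
    a hybrid coalescent / forward Wright-Fisher simulator of polygenic
    traits under stabilizing selection with per-ancestry optimum shifts,
    GWAS-like causal-variant ascertainment, trait-associated genomic
    region (TAGR) construction, evaluation utilities (true-positive rates,
    genetic-value differentiation, percentile thresholds), and curation of
    ancient reference panels in principal-component plus date space.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    igraph,
    vcfR,
    yaml,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
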