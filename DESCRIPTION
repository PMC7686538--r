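Package: mitonuclear
Title: Detecting Population-Discriminating Mitonuclear Genotype Combinations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A machine-learning pipeline for detecting combinations of
    mitochondrial and nuclear genotypes that discriminate human populations.
    Genotype states at gene and gene-pair level are encoded as
    reference-population frequency scores, classified with random forests
    under serial importance-ranked feature selection, and called
    population-specific by intersecting optimal feature lists across
    classifiers. Conventional population-genetics baselines (sliding-window
    linkage-disequilibrium pruning, Weir-Cockerham Fst with a
    label-permutation null, and discriminant analysis of principal
    components) are included for cross-validation of the machine-learning
    results, together with a three-population synthetic genotype generator
    (Balding-Nichols allele-frequency divergence, Hardy-Weinberg diploid
    sampling, and marginal-preserving planted mitonuclear interactions)
    that writes standard VCF/panel fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
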