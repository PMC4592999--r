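Package: crossalign
Title: Detection and Correction of Sample Mix-Ups in Experimental Cross
    eQTL Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to detect and correct sample mix-ups in expression
    genetic studies on experimental crosses. Expression arrays are aligned
    across tissues through correlations over probes with strong
    between-tissue correlation, and DNA samples are aligned to mRNA samples
    through k-nearest-neighbour classifiers that predict the genotype at
    large-effect local eQTL from expression alone. Includes multipoint
    genotype probabilities for an F2 intercross via a hidden Markov model
    with a genotyping-error model, single-position Haley-Knott regression
    LOD scores, genotype quality control (sex versus X-chromosome
    concordance, duplicate DNA detection, crossover counts), classification
    of inferred mislabelings by 96-well plate geometry, and a synthetic
    multi-tissue F2 study simulator with a ground-truth ledger of planted
    errors so that every detection stage is testable without external data.
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
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
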