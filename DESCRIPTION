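Package: paleobrain
Title: Brain and Body Mass Estimation and Encephalization Quotients for
    Fossil Cetaceans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calibrates allometric relationships between brain mass and
    endocranial volume and between occipital condyle width and body mass by
    phylogenetic generalized least squares with maximum-likelihood Pagel's
    lambda, applies them to estimate brain mass, body mass and
    encephalization quotients (EQ) in fossil cetaceans, accounts for the
    cranial adnexa and cerebrospinal fluid when relating brain mass to
    endocranial volume, and compares mean log10 EQ across geological time
    bins with one-way ANOVA followed by a Tukey HSD post-hoc test computed
    from the studentized-range distribution. Includes a seeded synthetic
    data generator (pure-birth trees, Brownian trait simulation, specimen
    tables with maturity structure) so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    nlme,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
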