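Package: canopyshift
Title: Temporal Beta Diversity, Trait Shifts, and Phylogenetic Mixed Models
    for Forest Resurvey Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies forest mesophication from paired-era canopy resurvey
    data. Implements the temporal beta diversity index (TBI) with gain/loss
    partitioning, Hill-number (q = 1) taxonomic, functional, and phylogenetic
    beta-diversity partitioning with permutation-null standardized effect
    sizes, community-weighted-mean shift tests, trait derivation and
    flammability PCA, Pagel's lambda phylogenetic-signal screening, and
    zero-inflated Poisson phylogenetic generalized linear mixed models with
    nested phylogenetic clustering, including the percent-variance-reduction
    statistic for trait explanation of clustering. A synthetic-data module
    generates trees, lambda-scaled Brownian traits, and paired-era community
    matrices with the full generative structure assumed by the models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    glmmTMB,
    MASS,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    phytools,
    lme4,
    withr
Config/testthat/edition: 3
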