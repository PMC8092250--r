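Package: kinhome
Title: Partitioning Host-Genetic and Shared-Home Contributions to the Childhood Gut Microbiome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a sibling-adoption analysis of childhood gut microbiome
    variation that separates host genetic relatedness from shared home
    environment. Provides community-level Generalized Dissimilarity Modeling
    with monotone I-spline transforms fitted by iteratively reweighted
    non-negative least squares, per-taxon negative-binomial and binomial
    mixed models with a kinship-structured child random effect and a
    household random effect estimated by penalized quasi-likelihood,
    likelihood-ratio and permutation tests for variance components,
    broad-scale pattern statistics (component chi-square test and
    taxonomic-order enrichment by resampling), and a synthetic adoption-cohort
    generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    lme4
Config/testthat/edition: 3
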