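Package: demosoc
Title: Demographic Correlates of a Sociality Continuum from Matrix
    Population Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Derives life-history traits, stable-structure-weighted vital
    rates, elasticities of population growth rate, and transient metrics
    (damping ratio, period of oscillation, reactivity, first-step
    attenuation) from stage-structured matrix population models, and links
    them to a five-level sociality continuum with body-mass-corrected
    phylogenetic comparative statistics: phylogenetic generalized least
    squares with Pagel's lambda, simulation-based phylogenetic ANOVA with
    post hoc letters, phylogenetic principal component analysis, and
    regularized iterative-PCA imputation of missing traits. A synthetic-data
    module generates ultrametric trees, body masses, sociality levels and
    matrix models with known ground truth so the full pipeline is testable
    without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    MASS,
    stats,
    utils,
    jsonlite
Suggests:
    phytools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
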