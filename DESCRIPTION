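Package: chronomorph
Title: Chronophylomorphospace Analysis of Size-Adjusted Morphometrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Comparative-morphometrics toolkit for mixed fossil and extant
    clades. Builds size-adjusted (Mosimann) trait spaces from linear
    measurements and ordains them by principal components; classifies
    specimens by linear discriminant analysis with leave-one-out validation;
    tests group separation with permutational MANOVA and sequential
    Bonferroni correction; time-scales composite phylogenies from fossil
    occurrence dates and molecular node dates with zero-length-branch
    resolution; quantifies phylogenetic signal by phylogenetic eigenvector
    regression and Blomberg's K; scores discrete character matrices with
    Fitch parsimony and ensemble fit indices; and projects phylogenies into
    trait space through time as chronophylomorphospaces with
    maximum-likelihood ancestral state estimates and confidence intervals.
    Includes seeded simulators for pure-birth trees, Brownian traits, and
    specimen-level measurement tables for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    MASS,
    phangorn,
    picante,
    vegan,
    optparse
Config/testthat/edition: 3
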