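Package: tauens
Title: Conformational Ensemble, Markov State Model, and Cross-Link Analysis
    for Aggregation-Prone Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for distinguishing aggregation-prone from
    aggregation-resistant peptide conformational ensembles, motivated by the
    tau repeat domain and its VQIVYK amyloid motif. Provides distance-map,
    centre-of-mass distance, RMSD, GROMOS-style clustering and beta-hairpin
    turn-register analyses of multi-model coordinate ensembles; a Markov
    state model engine with tICA dimensionality reduction, k-means
    discretization, implied timescales, Chapman-Kolmogorov validation,
    PCCA+ coarse-graining, mean first-passage times and transition path
    theory (committors, gross/net fluxes, pathway decomposition);
    NMR-derived neighbour-corrected secondary-structure propensities and
    r^-6-averaged NOE effective distances; and cross-linking mass
    spectrometry post-search analysis (identification filtering, replicate
    consensus, frequency normalization, contact-order and repeat
    classification, pattern clustering). Includes synthetic-data generators
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    igraph,
    jsonlite,
    MASS,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
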