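Package: flexfold
Title: Restraint-Based Ensemble Modeling of Flexible C5-Symmetric Channel Domains
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Integrative determination of flexible, five-fold symmetric
    membrane-protein domains from solution NMR and ESR observables.  Converts
    per-residue paramagnetic relaxation enhancement (PRE) intensity ratios,
    IPAP splittings, relaxation decay series, saturation-transfer pairs and
    amide temperature series into distance and hydrogen-bond restraints,
    turns inter-subunit DEER distance distributions into symmetric pentamer
    restraints, folds a coarse-grained C5-symmetric model by restraint-scored
    simulated annealing inside an iterative rank/cluster/reseed protocol,
    and validates the result with held-out-restraint Q-factors, pore-radius
    profiles, lateral-portal measurements, secondary-structure and disorder
    analysis.  A synthetic-data generator forward-models every observable
    from a known toy pentamer so the whole pipeline is testable at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    minpack.lm,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
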