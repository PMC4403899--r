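Package: prostab
Title: Structure-Based Prediction of Protein Stability Changes upon Mutation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the change in the free energy of unfolding (ddG) caused
    by single- and multi-point mutations directly from a wild-type protein
    structure. Distance-dependent residue-pair and contact statistical scoring
    functions (potentials of mean force) are compiled from known structures,
    normalized against expected energies and combined through a
    Wilcoxon-Mann-Whitney rank statistic. A seven-agent ensemble (multiple
    linear regression, neural networks and support vector regression, with
    specialists for stabilizing and destabilizing substitutions) yields an
    outlier-pruned consensus ddG together with a confidence estimate. The
    package additionally provides exhaustive, greedy and evolutionary searches
    for stabilizing or destabilizing multi-point mutants, and a screening mode
    that ranks candidate disulfide bridges from predicted ddG plus two
    geometric penalties.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    nnet,
    e1071
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
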