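Package: dooit
Title: Dual-Objective nu-SVR Model Selection with Iterative Feature
    Pruning for Solubility QSPR in Deep Eutectic Solvents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements the DOO-IT workflow for quantitative
    structure-property modelling of log mole-fraction solubility of
    pharmaceutical acids in deep eutectic solvents: COSMO-RS-derived
    descriptor engineering (energetic descriptors, binned sigma-potential
    descriptors, mixture weighting, relative descriptors), dual-objective
    nu-support-vector-regression hyperparameter search trading
    cross-validated mean absolute error against the support-vector ratio,
    Pareto-front extraction, one-standard-error candidate selection,
    permutation-importance backward feature pruning, multi-run stability
    aggregation, and composite multi-criteria final model selection. A
    synthetic-data generator with known ground truth makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    e1071,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
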