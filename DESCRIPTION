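Package: bnrecover
Title: Benchmarking Bayesian Network Scoring Functions for Structure Recovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation framework for evaluating how well decomposable
    Bayesian network scoring functions (MDL/BIC, AIC, BDeu, factorized
    normalized maximum likelihood) recover known generating structures.
    Provides discrete Bayesian network representation with maximum
    likelihood parameter fitting, logic (forward) sampling, globally
    optimal structure learning by dynamic programming over variable
    subsets, greedy hill climbing with tabu list and random restarts,
    supervised MDLP discretization and kNN imputation for preparing raw
    tables, and structural evaluation metrics including equivalence-class
    aware structural Hamming distance via CPDAG conversion.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
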