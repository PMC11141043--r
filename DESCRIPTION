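Package: genscore
Title: Configurable Multi-Parameter Scoring, Evaluation and Benchmarking
    for De Novo Molecule Generation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A configuration-driven scoring pipeline for iterative de novo
    molecular design: SMILES parsing and canonicalization with score
    caching, a library of self-contained scoring functions (descriptors,
    penalised logP, fingerprint and isomer similarity, substructure
    matching and alert filters, applicability-domain checks),
    transformation functions mapping raw scores to desirabilities in
    [0,1], aggregation functions (weighted sums and products, geometric
    mean, Pareto ranking), stateful diversity filters that penalise
    over-exploited chemotypes, and a benchmark mode with an evaluation
    budget. A companion metrics suite computes intrinsic metrics
    (validity, uniqueness, internal diversity, sphere-exclusion and
    Solow-Polasky diversity, scaffold, functional-group and ring-system
    diversity, alert filters) and extrinsic metrics against reference
    sets (novelty, nearest-neighbour and analogue similarity, fragment
    and scaffold similarity, outlier fingerprint bits, Wasserstein
    property distances). Deterministic fixture generators and a demo
    pool optimizer exercise the full loop without any external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
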