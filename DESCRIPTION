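Package: dagclimb
Title: Hill-Climb Causal Discovery with a Linear-Gaussian BIC Score
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Score-based discovery of directed acyclic graphs over
    standardized continuous variables.  Structure search is greedy hill
    climbing over single-edge additions, removals and reversals under
    expert-knowledge blacklists, scored with a decomposable linear-Gaussian
    Bayesian information criterion.  Learned graphs are quantified as
    recursive linear structural equation models with direct, indirect and
    total effects obtained by breadth-first path tracing and by matrix
    inversion; edge stability is assessed by a nonparametric bootstrap of
    the whole learn-and-fit procedure, and models learned on different
    cohorts can be compared via edge-set overlap.  Also provides variable
    standardization, correlation-threshold hierarchical clustering with
    first-principal-component aggregation, LMG relative-importance
    decomposition, and seeded linear-Gaussian data simulators for
    benchmarking structure and effect recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
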