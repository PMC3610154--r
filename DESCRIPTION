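Package: omicnet
Title: Network-Based Integration and Analysis of Omics Data
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A headless, scriptable toolkit for integrating structured
    experiment data (metabolite levels, enzyme activities, morphological
    measurements) with biological networks.  Provides an attributed
    directed multigraph model with readers and writers for GML, GraphML,
    SIF and the SBML topology subset; an experiment-data model with
    plain-text template, long-CSV and mapping-table input; identifier-based
    data mapping onto network nodes; statistical analysis (t-tests,
    Grubbs outlier test, David quicktest, hypergeometric enrichment),
    Pearson and Spearman correlation networks (1:n and n:n);
    self-organizing-map clustering of mapped profiles; structural network
    analysis (shortest paths, cycles, motifs, centralities); discrete
    Petri-net simulation with P/T-invariants and reachability graphs;
    constraint-based analysis of stoichiometric models (FBA, FVA,
    knockouts, robustness scans); automatic layouts and chart-annotated
    SVG/PNG/HTML rendering; and a synthetic-data generator emulating
    block-correlated ecotype panels for reproducible end-to-end workflows.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    xml2,
    pracma,
    stats,
    utils,
    tools,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    readxl,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
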