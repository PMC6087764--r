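Package: herbnet
Title: Network Pharmacology of Multi-Herb Formulas via ADME Screening and
    Bipartite Network Contribution Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for system-pharmacology analysis of multi-herb medicine
    formulas. Implements multi-criterion ADME screening of herbal components
    (oral bioavailability, Caco-2 permeability, drug-likeness, gastrointestinal
    absorption class), Tanimoto similarity for descriptor vectors and binary
    substructure fingerprints, bipartite component-target and target-pathway
    network construction with degree statistics and Cytoscape-readable exports,
    a per-component contribution score combining component degree, a two-herb
    affinity index and target degrees, hypergeometric over-representation
    analysis of target sets against disease or pathway annotation universes,
    per-herb physicochemical property comparison, seeded synthetic-data
    generators for every input, and an end-to-end pipeline with a JSON run
    report. Ships the component and target tables of the Zhi-zhu Wan
    (Zhishi-Baizhu) formula as packaged example data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
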