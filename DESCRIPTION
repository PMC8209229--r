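Package: fviiiRIN
Title: Residue Interaction Network Analysis of Coagulation Factor VIII
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds residue interaction networks (RINs) from protein
    structures of coagulation factor VIII (or any single-model protein PDB),
    profiles per-residue graph centrality (degree, betweenness, closeness,
    Burt's constraint, PageRank, k-core, HITS authority), classifies residue
    criticality (HDHB/LDHB/LDLB groups and Pareto-front super-critical
    residues), computes Shrake-Rupley solvent-accessible surface areas and
    relative exposure against Gly-X-Gly reference states, analyses
    binding-site neighborhoods, predicts alanine-mutant chromogenic activity
    with a median-probability classifier ensemble (SVM, naive Bayes,
    gradient-boosted trees), and sanitizes hemophilia A clinical mutation
    tables for positional enrichment tests. Ships deterministic synthetic
    generators (helical structures, activity tables, clinical tables) that
    exercise every stage with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    bio3d,
    e1071,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
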