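Package: borrownet
Title: Quantifying Lexical Borrowing Between Language Families from
    Root Presence/Absence Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing horizontal transfer (lexical borrowing)
    between language families from binary root-by-doculect matrices, using
    methods borrowed from gene-content phylogenetics. Provides readers and
    coding/filtering rules for root matrices with missing data and synonymy,
    GeneContent distances and similarity matrices, a from-scratch NeighborNet
    implementation (circular ordering plus nonnegative least-squares split
    weights with weight filtering and NEXUS SPLITS export), cross-family
    sharing and borrowing profiles aggregated by language cluster, a
    configurable criteria-based procedure for assigning the family of origin
    of a shared root, and a synthetic-data generator with ground-truth
    borrowing events (Yule family trees, Dollo root evolution, geographically
    structured directional borrowing) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    geosphere,
    jsonlite,
    pracma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
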