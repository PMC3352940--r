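Package: caudotheca
Title: Maximum-Parsimony Phylogenetics and Theropod Tail-Character Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for maximum-parsimony analysis of discrete morphological
    character matrices: NEXUS/TSV matrix parsing with polymorphic and missing
    cells, Fitch and Sankoff tree-length computation, per-character step
    bounds and ensemble homoplasy statistics (CI, HI, RI, RC), heuristic tree
    search by random stepwise addition with NNI/SPR/TBR branch swapping,
    exact exhaustive search on small instances, strict consensus, Bremer
    decay indices by converse-constraint search, and ACCTRAN/DELTRAN
    ancestral-state optimization with synapomorphy listing. Includes a module
    for the evolution of the dromaeosaurid tail skeleton: parsing and
    discretizing tabulated caudal characters (caudotheca, hemicaudotheca,
    transition points, centrum elongation), mapping them on a coelurosaur
    phylogeny, classifying tail conditions, and bounding the cranial extent
    of the caudotheca from incomplete specimens. A seeded simulator for
    Mk-style discrete characters on random trees, with fossil-style
    fragmentary missing data, supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
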