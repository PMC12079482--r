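Package: cirtop
Title: Circuit Topology and Conformational Ensemble Analysis for Disordered Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for conformational ensembles of intrinsically
    disordered proteins, built around the androgen receptor N-terminal
    transactivation domain and its polyglutamine-expanded variant. Provides
    residue-contact analysis under atom-pair distance criteria, circuit
    topology profiling of intra-chain contact networks (series, parallel and
    cross relations, per-residue inverse-parallel profiles, configuration-space
    densities), per-residue fluctuation and helicity metrics, GROMOS-style
    conformational clustering with coverage-based representative selection,
    and interface fingerprinting of two-chain docking poses (typed
    interactions, region binding fractions, motif blockade and solvent
    accessibility). A seeded synthetic-conformer generator with planted,
    self-verified ground truth makes every stage testable without external
    trajectory data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    seqinr,
    stats,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp
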