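Package: abagbench
Title: Curation Toolkit for Antibody-Antigen Docking Benchmarks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and maintaining non-redundant antibody-antigen
    docking benchmark datasets from experimental structures. Reads and writes
    ATOM-only PDB coordinate files, screens sequence-search hit tables for
    unbound partner structures, quantifies bound/unbound conformational change
    (RMSD, interface RMSD, fraction of non-native contacts, buried surface
    area, CDR loop RMSD), classifies docking difficulty into Rigid, Medium and
    Difficult, removes redundant complexes by greedy maximum-degree pruning of
    a sequence-and-structure similarity graph, and incrementally updates a
    stored benchmark with newly released complexes. A synthetic-fixture
    generator produces toy antibody-antigen complexes with controlled
    conformational perturbations so the whole pipeline can be exercised
    without downloading structures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
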