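Package: monomerize
Title: Infer the Monomeric Structure of Small Biological Polymers from SMILES
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reconstructs the monomeric (building-block) structure of small
    biological polymers such as nonribosomal peptides from their atomic
    structure given as SMILES. Monomers from a database are truncated by
    chemical reaction rules into families of residues organised in a directed
    acyclic graph; residues are located on the target polymer with a
    branch-and-bound subgraph-isomorphism algorithm over line (bond) graphs,
    guided by a frequency-learned selectivity index; and a greedy tiling with
    local modulation and branch-and-bound refinement selects non-overlapping
    residues maximising atom coverage. Includes a synthetic-polymer generator
    with internal ground truth and evaluation metrics (coverage, correctness,
    recall/precision).
License: MIT + file LICENSE
Depends: R (>= 4.0)
Imports:
    ChemmineOB,
    igraph,
    jsonlite,
    stats
Encoding: UTF-8
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
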