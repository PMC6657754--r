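Package: allonet
Title: Elastic-Network Community Analysis of Allosteric Protein Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes allosteric signal transduction in multi-chain protein
    complexes from coordinates alone. Parses PDB structures, coarse-grains them to
    C-alpha or residue center-of-mass bead models, builds anisotropic elastic
    networks and residue cross-correlation matrices from normal modes, partitions
    the correlation-weighted residue contact network into dynamical communities by
    iterative removal of maximal-betweenness edges, flags multichain communities
    and interior critical residues, classifies ligand-binding sites as multichain
    or single-chain, computes solvent-accessible surface and interface metrics,
    and provides the cohort statistics (tests of proportions, Wilcoxon rank-sum
    tests, ANCOVA with an apo covariate) used to compare binding-site classes and
    apo-holo pairs. A seeded generator of synthetic multi-chain bead complexes
    with planted rigid clusters and interface or single-chain ligand pockets makes
    every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    graphics,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    Biostrings,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
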