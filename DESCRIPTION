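Package: geneBirthDynamics
Title: Branch-Wise Dating and Evolutionary Profiling of Duplicated and
    Putative De Novo Genes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to classify new gene birth events on a rooted species
    tree from orthogroup and duplication tables, normalize per-branch
    birth rates by branch length, test purifying selection with a
    normalized PN/PS statistic built on a neutral expectation from codon
    composition and an intronic mutation matrix, contrast observed and
    expected amino-acid substitutions under a single-nucleotide neutral
    model, profile protein sequence properties (length, isoelectric
    point, residue-class composition), and detect maximal unique matches
    (MUMs) clustered into genomic synteny blocks. Includes seeded
    synthetic-data generators with ground-truth tables for end-to-end
    recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rcpp,
    vcfR,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    readxl,
    jsonlite
Config/testthat/edition: 3
biocViews: Phylogenetics, ComparativeGenomics, Software
RoxygenNote: 7.3.3
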