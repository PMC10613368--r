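Package: cfFragmentomics
Title: Multidimensional Fragmentomic Analysis of Cell-Free DNA
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for multidimensional fragmentomic profiling of cell-free
    DNA (cfDNA) from paired-end whole-genome sequencing of single-stranded
    libraries. Reconstructs fragments from aligned read pairs with a hybrid
    read-length/insert-size metric, characterizes fragment-size
    distributions (mononucleosomal peaks, 10 bp periodicity, slope-change
    threshold between nucleosome-free and nucleosome-bound fragments),
    computes BPM-normalized protein footprints around annotation anchors,
    builds fragment end-motif position frequency matrices, attributes
    fragment end positions to RepeatMasker-style repeat classes, and
    reconstructs extrachromosomal circular DNA from split-read junction
    evidence. Ships a deterministic cfDNA read simulator with full
    ground truth so every analysis stage is verifiable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    data.table,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
biocViews: Sequencing, Epigenetics, WholeGenome, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
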