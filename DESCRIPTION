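Package: msytools
Title: Identification, Validation and Exploitation of Y-Linked Scaffolds
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An integrated in silico toolkit for assembling the male-specific
    region of the Y chromosome (MSY) from unplaced scaffolds of a genome
    assembly. Infers sample sex from mapping rates against male seed
    sequences, classifies scaffolds as Y-, X- or autosome-linked by the
    female/male read-depth (AD) ratio, by single-copy k-mer profiling
    against sexed read dictionaries (YGS) and by homology voting, and
    integrates the three calls by intersection and union. Orders Y markers
    on a radiation-hybrid panel via two-point LOD statistics, linkage
    grouping and travelling-salesman marker ordering with laboratory-error
    flagging. Applies the haploid Y-SNP quality cascade (hard filters,
    female-site exclusion, biallelic/MAF/call-rate filters), concatenates
    surviving SNPs into an alignment for phylogenetic and skyline analyses
    and derives the rescaled per-column mutation rate. Ships seeded
    simulators for genomes, sexed depths and reads, radiation-hybrid panels
    and VCFs with known ground truth so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    data.table,
    igraph,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
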