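Package: hemidyad
Title: Dyad-Resolved DNA Hemi-Methylation from Methylation-Dependent
    Restriction Digests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Resolves the methylation status of single CpG and CHG dyads
    (unmethylated, hemi-methylated on either strand, fully methylated) from
    the cut-edge geometry of fragments produced by the methylation-dependent
    restriction enzyme MspJI, which cleaves 9/13 bp downstream of a
    methylated CNNR site. Provides a seeded digestion and library simulator,
    an in-silico whole-genome digest, a fragment-to-dyad caller with
    UMI-aware deduplication, efficiency-based count normalization and its
    inversion, a hairpin-bisulfite readout simulator used as an independent
    cross-validation oracle, and downstream analyses: motif-cluster
    classification, orientation-aware hemi-methylation profiles, region
    signal annotation, and allele-specific methylation tests with FDR
    control.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    withr,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: DNAMethylation, Epigenetics, Sequencing, Software
RoxygenNote: 7.3.3
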