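Package: minorsplice
Title: Minor Intron Retention and Splice-Site Usage Analysis from Aligned RNA-seq Reads
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies minor (U12-type) intron retention from aligned RNA-seq
    reads using the splice-site unusage (SSun) statistic, the ratio of reads in
    fixed-width intronic versus exonic windows flanking each exon/intron
    boundary. Also quantifies competing splice-junction usage (normal versus
    cryptic sites) from junction-spanning reads, scores RIP-seq enrichment of
    protein-associated RNAs against mock controls, performs delta-delta-Ct
    relative quantification of RT-qPCR data, and applies concordant
    multi-contrast differential-expression filters to RNA count and protein
    abundance tables. A seeded simulator generates gene models, aligned reads
    with controlled intron retention and cryptic splicing, and replicate
    count/abundance tables with planted effects, so every stage can be
    validated against ground truth.
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
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    GenomicAlignments,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: RNASeq, Transcriptomics, AlternativeSplicing, DifferentialExpression, Sequencing
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'annotation.R'
    'stats-utils.R'
    'rip.R'
    'diffexp.R'
    'simulate.R'
    'junctions.R'
    'minorsplice-package.R'
    'qpcr.R'
    'ssun.R'
    'pipeline.R'
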