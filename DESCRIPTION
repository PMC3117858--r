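Package: rrlchip
Title: Reduced-Representation SNP Discovery and Genotyping Array Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for designing a medium-density SNP genotyping array from
    pooled reduced-representation sequencing, modelled on the design of the
    chicken 60K BeadChip. Covers in-silico restriction digestion and fragment
    size selection, short-read quality filters, pileup-based SNP calling from
    pooled populations with minor-allele-frequency estimation by read
    counting, priority- and spacing-driven panel selection, array performance
    classification, and two-point linkage placement of unmapped markers with
    Kosambi map distances. A synthetic-data layer generates genomes, planted
    SNPs, pooled reads and full-sib mapping families with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    data.table,
    jsonlite,
    igraph,
    rtracklayer,
    Rsamtools
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
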