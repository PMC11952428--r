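Package: fiberfoot
Title: Single-Fiber Methylation Footprinting of Protein-DNA Binding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis of antibody-directed DNA methylation experiments read
    out by modified-base long-read sequencing. Parses MM/ML modified-base
    tags from aligned SAM/BAM records, builds motif-centered 6mA and 5mCpG
    enrichment profiles with control subtraction, fits exponential decays to
    nucleosome-phased methylation peaks flanking bound sites, renders
    single-read methylation matrices, contrasts haplotype-resolved alleles at
    imprinted loci, scans motifs and classifies sites by genomic region, and
    quantifies chromosome-associated immunofluorescence signal in 3D confocal
    stacks. Includes a single-fiber simulator with known ground truth for
    validation and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
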