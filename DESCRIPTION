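Package: epiprofile
Title: Chromatin Organization of CpG Islands and Exons from Tag Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying chromatin organization at CpG islands,
    promoters and exon-intron structures from short-read tag data.
    Builds normalized read-count (NRC) tracks from BED tag files with
    fragment extension and fixed-width binning, detects CpG islands by
    the Gardiner-Garden criteria, scores DNA bendability from
    trinucleotide parameters, classifies exons (non-coding, initial,
    internal, last coding) with UTR/CDS segmentation, computes
    CGI-anchored, TSS-anchored and ten-bin exon/intron metagene
    profiles, measures exon inclusiveness and skipped-exon classes from
    RNA-seq, applies weak-splice-site exon filters, computes
    open-chromatin odds-ratio enrichment, bisulfite methylation levels
    and pol II elongation efficiency, and ships a seeded synthetic
    genome/epigenome generator with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml,
    Biostrings,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
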