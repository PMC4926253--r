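Package: txevents
Title: Chimeric RNAs, SNPs and Allele-Specific Expression from RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for transcriptome-event analysis of bulk RNA-seq in
    prenatal porcine skeletal muscle and comparable systems: consensus
    calling and structural classification of chimeric (fusion) RNAs with
    canonical GT/AG junction verification and junction-spanning read
    counting; hard and cluster filtering of RNA-seq SNPs with consequence
    annotation, substitution-spectrum, dbSNP-novelty and QTL-overlap
    summaries; allele-specific expression calling from heterozygous-site
    allele counts via an exact binomial test with Benjamini-Hochberg FDR
    control and allelic-ratio cutoffs; and RPKM quantification with
    detection and abundance binning. A deterministic, seeded synthetic-data
    generator emits a toy genome, annotation, variants, allele counts,
    fusion candidates, junction reads, QTL regions and a known-SNP
    catalogue with machine-readable truth labels, so the whole pipeline is
    testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    utils,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
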