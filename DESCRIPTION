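Package: lilrseq
Title: Allele Discovery and Splice-Isoform Annotation for LILRB Long-Read
    Amplicon Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a long-read amplicon workflow for
    characterizing allelic diversity and alternative splicing of the
    inhibitory leukocyte immunoglobulin-like receptor genes LILRB1 and
    LILRB2 in Old World monkey species. Provides an exon-intron gene model
    with protein-domain and ITIM annotation, a synthetic-data generator for
    barcoded circular-consensus amplicon reads with ground truth, read
    quality filtering and dual-barcode demultiplexing, exact-match allele
    calling with iterative reference-library growth and novel-allele
    confirmation, transcript-to-genomic spliced alignment with
    splice-event classification and protein-consequence annotation,
    neighbor-joining phylogenetics (Jukes-Cantor, Tamura-Nei and
    Nei-Gojobori distances) with bootstrap support and lineage-based
    allele nomenclature, and summary diversity statistics (variability
    profiles, per-exon synonymous/non-synonymous mutation density, domain
    sharing, residue frequency tables).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    phangorn,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
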