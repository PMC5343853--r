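Package: pamparray
Title: EST Library Enrichment, Oligonucleotide Microarray QC and
    Differential Expression for PAMP-Stimulated Macrophages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, reproducible implementation of a fish
    immunogenomics analysis workflow: clustering of expressed sequence
    tags (ESTs) from bacterial- and viral-primed cDNA libraries with a
    contig-frequency enrichment rule, quality control and
    percentile-shift normalization of single-channel oligonucleotide
    microarray scans, per-treatment differential expression with signed
    fold changes and Venn partitioning, Fisher exact GO term enrichment,
    and Pfaffl efficiency-corrected RT-qPCR cross-validation. A
    synthetic-data module generates EST libraries, array experiments and
    qPCR tables with known ground truth so that every stage of the
    pipeline is testable without access to the original scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
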