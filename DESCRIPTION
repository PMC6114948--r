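Package: somage
Title: Age Association of Somatic Genomic Alterations in Tumor Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for relating somatic genomic and epigenomic
    alterations to patient age in tumor exome cohorts. Filters MAF-like
    somatic mutation tables (same-patient deduplication, multi-gene
    ambiguity removal, tandem-repeat context exclusion), builds 96-channel
    pyrimidine-normalized trinucleotide mutation profiles, refits per-tumor
    exposures to a fixed 30-signature catalog by bound-constrained least
    squares, computes per-patient SNP, copy-number and methylation burden
    statistics, runs Spearman age-association screens with bootstrap
    confidence intervals and Benjamini-Hochberg false discovery control,
    classifies patients into mismatch-repair signature subgroups, and
    projects gene-level alteration matrices onto gene sets with
    single-sample gene set enrichment analysis (ssGSEA). Includes a
    synthetic cohort generator with ground truth so every stage is
    verifiable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    pracma,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
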