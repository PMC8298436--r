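Package: mprastat
Title: Allelic and Drug-Interaction Statistics for Massively Parallel
    Reporter Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Statistical machinery for barcode-level massively parallel
    reporter assay (MPRA) screens of regulatory variants: RNA/DNA barcode
    activity quantification and filtering, per-SNP allelic t-tests with
    empirical p-values drawn from negative-control ("basal") barcode
    pseudo-comparisons, allele-by-drug linear mixed models with
    empirical F-statistic nulls and likelihood-ratio validation of
    interactions, position-weight-matrix allelic motif perturbation
    scoring, resampling-based transcription-factor motif enrichment with
    concordance statistics, and ChIP-peak overlap counting. Includes a
    synthetic-data generator with known ground truth for end-to-end
    validation and power analysis of the assay design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
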