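Package: isopanel
Title: Targeted Long-Read RNA-Seq Isoform Panel Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of targeted long-read RNA sequencing of gene
    panels. Provides isoform-level CPM normalization and proportion estimates,
    on-target rate and capture fold-enrichment metrics, spike-in detection
    limits, percent-spliced-in (psi) for cassette exons from isoform
    abundances, detection of tumor subtype-associated isoforms (t-test with
    Benjamini-Hochberg FDR and an effect-size floor), a three-stage outlier
    procedure for tumor-aberrant isoforms (chi-square homogeneity screen,
    one-tailed binomial post hoc, replicate/recurrence/canonical filters),
    structural classification of alternative-splicing events against the
    canonical isoform, NMD-target prediction by the 50-nt rule, and 1x-tiling
    capture probe design. A seeded synthetic-data generator emulates the
    multi-cell-line count matrices, spike-in ladders, and toy gene models the
    pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
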