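Package: ampliCNV
Title: Copy Number Difference Calling from PCR-Amplicon Read Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects copy-number differences between a sample and a control
    enriched with the same multiplex PCR primer panel, using per-primer read
    counts. Log2 count ratios are median-normalized, grouped into positional
    (or gene-annotation) clusters, pruned of outliers by an iterative
    Shapiro-Wilk loop, and tested with a weighted one-sample t-test using an
    effective sample size derived from count weights. Calls carry a
    dispersion-corrected Phred-like significance score (Q), a precision score
    (P) for the copy-number estimate, and confidence bounds, and are written
    as VCF 4.2 structural-variant records. A seeded negative-binomial
    amplicon-count simulator with planted copy-number events supports
    end-to-end evaluation (sensitivity, specificity, ROC) without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    jsonlite,
    optparse,
    withr
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation
Config/testthat/edition: 3
RoxygenNote: 7.3.3
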