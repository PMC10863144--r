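Package: somaticaction
Title: Somatic Variant Prioritization, Actionability Tiering and Xenograft
    Fidelity Analysis for Pediatric Tumor Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis toolkit for precision-medicine tumor
    sequencing cohorts, with neuroblastoma relapse cohorts as the motivating
    application. Implements somatic, germline and tumor-only small-variant
    filtration cascades with per-rule audit trails; selection of actionable
    copy-number variants (biallelic tumor-suppressor deletions and focal
    oncogene amplifications); tumor mutational burden and
    microsatellite-instability threshold calls; expression-outlier detection
    from CPM-normalized counts with hypergeometric overlap tests; two-tier
    clinical actionability grading with drug-mechanism concordance checks;
    and genomic-fidelity quantification of patient-derived xenograft
    generations and 3D tumor-sphere models via VAF matrices, correlation,
    Ward clustering, PCA, conserved-variant fractions and Mann-Whitney
    VAF-shift tests. A deterministic synthetic-cohort generator with a
    planted-lesion truth ledger makes every stage testable without access
    to patient sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    GenomicRanges,
    IRanges,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    jsonlite
Config/testthat/edition: 3
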