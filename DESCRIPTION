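Package: peakladder
Title: Distance-Ladder Enrichment and Matched-Random Null Models for
    Differential Chromatin Accessibility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links differential chromatin-accessibility peaks (ATAC-seq) to
    differential gene expression by expanding peaks over a ladder of genomic
    distances, counting encompassed transcription start sites, and testing
    enrichment of differentially expressed genes with upper-tail
    hypergeometric probabilities against an empirical null built from
    width-matched random peak sets. Also provides region-overlap enrichment
    tests for enhancer, super-enhancer and transcription-factor binding-site
    catalogues, peak post-processing (high-depth artifact exclusion,
    cross-condition merging, max-group-mean and q-value/fold-change
    thresholding), median-equalization signal normalization with metaplots
    and per-region read counts, and a seeded synthetic-data generator that
    emulates the full input bundle with planted peak-gene linkage so the
    whole pipeline can be exercised and calibrated without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
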