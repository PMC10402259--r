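Package: riboclean
Title: Contamination-Aware Analysis of RiboTag/TRAP Translatome RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for paired IP/input RNA-seq designs such as
    RiboTag or TRAP translatome profiling. Implements relative log expression
    (RLE, median-of-ratios) size factors, low-count filtering, per-gene
    negative binomial generalized linear models with Wald and likelihood
    ratio tests, the fraction-by-condition interaction contrast measuring
    differential cell-type enrichment, a two-arm filtration algorithm that
    removes ambient-contamination-driven differential expression calls,
    hypergeometric gene-set overlap tests with representation factors,
    resampling z-score operon enrichment, marker-panel and delta-delta-Ct
    quality control, and a negative binomial cell-type-mixture simulator
    of contaminated immunoprecipitation libraries with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    jsonlite
Config/testthat/edition: 3
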