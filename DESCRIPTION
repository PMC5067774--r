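Package: isomirTT
Title: IsomiR Tailing-and-Trimming Analysis for Small RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies small RNA-seq reads by their 3' end state relative to
    a miRNA precursor (templated extension, non-templated tailing, trimming),
    computes per-miRNA adenylation and degradation ratios that summarise the
    PAPD5/PARN tailing-and-trimming turnover pathway, quantifies precursor
    sub-regions as a processing proxy, and compares these metrics between
    sample groups with Student's t-test. Includes a kinetic simulator of the
    tailing-and-trimming chain so the whole pipeline can be exercised end to
    end against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    Rsamtools,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
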