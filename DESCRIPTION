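Package: rarecnv
Title: Case-Control Rare Copy-Number-Variant Burden Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for case-control analysis of rare copy number
    variants (CNVs) called from SNP arrays. Reads PennCNV-style call files,
    applies per-sample quality control (call-count and LogR-ratio noise
    thresholds), post-processes calls (gap-fraction merging of fragmented
    neighbouring calls, minimum marker-count filtering, removal of calls in
    centromeric/telomeric regions), builds size-stratified burden tables with
    one-sided Fisher exact tests on carrier counts, estimates the case excess
    of large-CNV carriers with Wald confidence intervals and odds ratios,
    detects gene regions recurrently rearranged in cases but never in
    controls, checks carrier status against ancestry principal components and
    genotyping batch, calls gene-level CNVs from MLPA probe ratios, classifies
    trio inheritance (de novo versus inherited), and aggregates SNP-based and
    MLPA evidence per gene. A synthetic-cohort generator with full ground
    truth makes every stage testable without access to raw genotype data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    IRanges,
    withr,
    stats,
    utils
Suggests: testthat (>= 3.0.0), jsonlite, knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
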