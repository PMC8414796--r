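Package: shortcall
Title: Triaged Short-Read SNV and Indel Calling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A lightweight short-read germline variant caller. Candidate SNV
    and indel sites are recognised from pileup summaries of sorted alignments,
    triaged into high-confidence, low-confidence, and tandem-repeat or
    low-complexity categories, and called with a category-specific method: a
    direct binomial genotype model for clean sites, partial-order-alignment
    consensus for locally complex sites, and de Bruijn graph local assembly
    for repeat regions. Includes a synthetic diploid read simulator with truth
    VCFs and a precision/recall/F1 evaluator so the whole pipeline can be
    exercised hermetically.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    withr,
    methods,
    parallel,
    generics,
    ggplot2,
    Biostrings,
    IRanges,
    GenomicRanges,
    Rsamtools,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    jsonlite,
    optparse,
    stringr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
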