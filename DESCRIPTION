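Package: asmcurate
Title: Curation and Evaluation Toolkit for Same-Species Genome Assembly Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements the comparative curation computations used when a new
    long-read genome assembly is evaluated against an established reference of
    the same inbred strain: discovery of reference gap fills with
    reciprocal-best-hit filtering, construction of a chain/net liftover between
    the two assemblies via an internal minimizer seed-and-chain micro-aligner,
    resolution of recurring multi-strain variants against the new assembly,
    consensus calling over structural-variant callsets from two technologies,
    repeat-class composition and enrichment of consensus unaligned regions, and
    QUAST-style assembly statistics (scaffold splitting, Nxx, k-mer
    completeness). A synthetic-data module generates reference/assembly pairs
    with planted gaps, variants, structural variants and repeat annotation so
    that every stage is testable end-to-end with machine-readable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rcpp,
    jsonlite,
    rtracklayer,
    vcfR,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
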