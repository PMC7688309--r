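Package: atacage
Title: Age-Dynamic Chromatin Accessibility and Regulatory Variant Analysis for Single-Nucleus ATAC-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Complexity-corrected relative accessibility scores for
    single-nucleus ATAC-seq peak-by-cell matrices, depth-corrected
    cell-fraction statistics, ensemble promoter co-accessibility via
    distance-penalized sparse partial correlation over metacells,
    pseudobulk negative-binomial detection and Davies-Bouldin K-means
    clustering of age-dynamic peaks, single-nucleus expression fractions,
    and allele-aware regulatory-variant scoring (exact PWM match p-values
    and k-mer delta scores with a permutation null). Includes synthetic
    cohort and genome generators with planted ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Matrix,
    MASS,
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    jsonlite
Config/testthat/edition: 3
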