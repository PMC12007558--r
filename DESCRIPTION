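Package: harmonybench
Title: Benchmarking Scanner Harmonisation of Imaging-Derived Phenotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying and removing scanner effects in
    travelling-heads neuroimaging studies, where the same subjects are
    scanned on several MRI systems. Provides a synthetic cohort generator
    with known ground-truth scanner effects, between-session similarity
    matrices built from category-wise Spearman correlations, the
    three-baseline coefficient-of-variation framework (within-scanner,
    between-scanner and biological variability), scanner bias and image
    quality metric z-scoring, between-scanner subject-ranking consistency
    with a permutation null, and from-scratch parametric empirical-Bayes
    ComBat and CovBat harmonisation with covariate preservation, together
    with a pre/post harmonisation evaluation pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    sva,
    optparse,
    withr
Config/testthat/edition: 3
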