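Package: intenrich
Title: Integrative Set Enrichment Testing Across Omics Platforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint gene-set enrichment testing for matched two-platform
    studies (e.g. transcriptomics plus metabolomics). Implements competitive
    tests (Fisher's exact test on the 2x2 differential-by-membership table,
    logistic regression of set membership on the absolute t-statistic) and
    the self-contained sum-of-squared-statistics test with a subject-label
    permutation null, together with their two-platform extensions:
    concatenation of element lists, Fisher's chi-squared p-value combination,
    a 2-degree-of-freedom Wald test, and a 2-dimensional Mahalanobis-distance
    permutation p-value against the cloud of null statistic pairs. Includes
    the disjoint-set and heterogeneous-set simulation models used to
    characterise Type-I error and ranking performance of the tests, an
    evaluation harness (per-set rejection frequencies and the rank-sum
    metric), TSV/GMT input-output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
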