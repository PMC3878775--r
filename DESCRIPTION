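Package: betaharmony
Title: Harmonisation, Imputation and Query Toolkit for 450K-Style DNA
    Methylation Beta Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for combining Illumina HumanMethylation450-style beta-value
    matrices from heterogeneous studies into a single harmonised resource.
    Provides beta-value computation from channel intensities, array-level
    quality control, nearest-neighbour graphs built from Euclidean distances on
    random probe subsamples, k-nearest-neighbour imputation of missing betas,
    quantile normalisation of each array against its own neighbourhood, banded
    Euclidean distances for diagnosing batch effects at different
    beta-difference scales, F-test calling of differentially methylated
    positions with Benjamini-Hochberg correction and directional concordance
    validation, a synthetic-data generator with bimodal beta structure, and a
    local repository with sample/probe/region query semantics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    mclust,
    stats,
    utils,
    withr
Suggests:
    ape,
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
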