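Package: ProteoImpute
Title: Missing-Value Imputation and Benchmarking for Quantitative Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for imputing missing values in label-free quantitative
    proteomics abundance matrices. Implements classical per-protein fills
    (half-minimum, mean), sample- and protein-wise k-nearest-neighbour
    imputation, four low-rank matrix-factorization imputers (probabilistic
    PCA, NIPALS, iterative SVD imputation, singular value thresholding),
    fused regularization matrix factorization that integrates within-data
    or external sample similarity, and a convex-analysis-of-mixtures
    strategy that models samples as nonnegative mixtures of archetypes and
    imputes on the original intensity scale. Includes simulation of
    MCAR/MNAR/mixed missingness, proportional masking of authentically
    incomplete data, and an RMSE/NRMSE/sum-of-ranks benchmarking harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
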