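Package: lcgrad
Title: Connectopic Gradient Mapping of the Locus Coeruleus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes voxel-wise functional-connectivity gradients within a
    small region of interest (the locus coeruleus) from 4D BOLD data:
    connectivity fingerprints against an atlas parcellation, eta-squared
    similarity, connectivity-preserving graph construction, Laplacian
    eigenmaps, and a third-order trend-surface summary of each gradient's
    spatial layout per hemisphere via evidence-maximized Bayesian ridge
    regression. Includes sliding-window behavioral analysis with nested
    F-tests and adjusted partial R-squared, per-year age models, partial
    Spearman correlations, Calinski-Harabasz clusterability, bootstrap
    MANOVA group contrasts with Mann-Whitney post hocs and Benjamini-
    Hochberg correction, plus a phantom generator that plants a known
    rostro-caudal gradient and behavioral couplings for validation.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
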