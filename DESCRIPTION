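Package: hdwm
Title: White-Matter Microstructure Pipeline for Premanifest Huntington
    Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative white-matter microstructure analysis for
    premanifest Huntington disease cohorts: magnetization transfer ratio
    (MTR) mapping, diffusion tensor fitting restricted to low b-values,
    restricted signal fraction (FR) estimation under a composite hindered
    and restricted diffusion model, free-water signal fraction mapping,
    callosal tractometry, tract-based cluster analysis (TBCA) with
    permutation family-wise error inference over a hypervoxel template,
    and the accompanying group statistics (varimax PCA with adequacy
    tests, Type III ANCOVA with simple-slopes moderation, Spearman and
    partial Spearman correlation families with Bonferroni correction).
    Includes a synthetic phantom and cohort generator so the entire
    pipeline can be exercised end-to-end without access to MRI data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    tibble,
    RNifti,
    minpack.lm,
    car,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
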