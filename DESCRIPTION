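Package: phenomet
Title: Two-Stage Factor-Analytic Analysis of Multi-Environment Trials and
    Phenomic Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for decision support in plant breeding from
    high-throughput field phenotyping (HTFP) of multi-environment trials
    (MET). Implements a two-stage weighted linear mixed-model analysis:
    stage one fits per-year-site spatial models (tensor-product P-spline
    surface, random row/column effects, weighted plot residuals) and
    returns genotype BLUEs with weights; stage two fits across-year-site
    models with identity, heterogeneous (Diag), or factor-analytic
    (reduced-rank plus Diag) genotype-by-environment covariance by
    restricted maximum likelihood, with full-likelihood information
    criteria for model selection. Includes FAST-style rotation of
    factor loadings into overall performance (OP) and stability (RMSD)
    indices, generalized heritability (Cullis) and repeatability (Oakey),
    bivariate genetic correlations, phenomic prediction of target traits
    from intermediate HTFP traits with partial least squares and random
    forests under unseen-environment and unseen-genotype cross-validation,
    selection-efficiency evaluation, and a synthetic MET generator with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    ranger,
    splines,
    stats,
    utils
Suggests:
    jsonlite,
    mixOmics,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
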