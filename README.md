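# phenomet

Decision support for plant breeding from high-throughput field phenotyping
(HTFP) of multi-environment trials (MET). The package implements the full
statistical chain needed to run *phenomic selection* — selecting for target
traits (yield, grain protein) predicted purely from intermediate
image-derived traits — in a winter-wheat variety-testing setting:

1. **Stage 1** — per-year-site weighted spatial mixed models
   (tensor-product P-spline surface, random row/column effects, plot
   weights `w = 1/SE²`), returning genotype BLUEs with weights and Oakey
   repeatability.
2. **Stage 2** — across-year-site REML models for the adjusted means with
   `Id`, `Diag`, or factor-analytic (`FA1`/`FA2`, reduced-rank + diagonal
   lack-of-fit) genotype-by-environment covariance; Cullis heritability;
   bivariate genetic correlations; BIC model selection on full
   log-likelihoods with the trait-screening rule for complex G×E.
3. **FAST** — rotation of the factor loadings to principal axes and the
   per-genotype overall performance (OP = mean first-factor loading ×
   first score) and stability (RMSD over higher factors) indices.
4. **Phenomic prediction** — PLS (in-package NIPALS) and random forest
   (`ranger`) regression of target traits on C/T/Q intermediate traits
   under unseen-environment / unseen-genotype / unseen-both and repeated
   k-fold cross-validation, with tuning, RMSE/nRMSE/Spearman metrics and
   feature importance (jackknife for PLS, 50-run permutation for RF).
5. **Selection efficiency** — the gain from adding an OP-prediction
   threshold on top of breeders' selections, plus protein-per-area
   trade-off arithmetic.

A synthetic MET generator (`sim_config()` / `simulate_met()`) reproduces
the study design — 45 genotypes, 5 year-sites, 3–4 replicates, ~20% of
genotypes missing per year-site, heteroscedastic plot SEs, FA G×E for
yield, linked secondary traits, ordinal breeder decisions — with known
ground truth, so every estimator is validated by parameter recovery.

The REML engine underneath (`reml_fit()`) is generic: pluggable covariance
structures (`vs_id`, `vs_diag`, `vs_us2`, `vs_rr`, `vs_rr_diag`), weighted
or structured residuals, sparse mixed-model equations, full-likelihood
information criteria, BLUPs and prediction-error variances.

## Worked example

```r
library(phenomet)

cfg <- sim_config(seed = 42)          # study-like trial, known truth
sim <- simulate_met(cfg)

# stage 1: genotype BLUEs with weights, per year-site
blues <- do.call(rbind, lapply(names(cfg$year_sites), function(s) {
  stage1_blues(fit_stage1(subset(sim$plots, trait == "yield" & year_site == s),
                          mode = "BLUE"))
}))

# stage 2: G x E model choice for the target trait
rep <- select_gxe_model(blues, role = "target")
rep
#> GxE model report for trait: yield
#>  model      bic loglik_full converged
#>     Id 293.0435   -125.7499      TRUE
#>   Diag 309.0111   -123.3478      TRUE
#>    FA1 326.5738   -121.7433      TRUE
#>    FA2 343.1277   -119.6343      TRUE
#> selected: Id

# the simulated trial happens to show mild GxE; force the FA2 dissection
fa  <- fit_fa(blues, n_factors = 2)
st  <- op_rmsd(rotate_loadings(fa))
head(st, 3)
#>   genotype       op       rmsd
#> 1     G001 6.678000 0.01724034
#> 2     G002 5.396607 0.02213938
#> 3     G003 7.483413 0.04579751

heritability_cullis(fit_overall(blues, "Id"))
#> [1] 0.9550265
cor(st$op, sim$truth$op_true[st$genotype] + mean(cfg$env_intercepts))
#> [1] 0.9696002
```

`st$op` is on the t/ha scale (the mean year-site intercept is added back);
`rmsd` is the root-mean-squared deviation of the higher-factor G×E effects
over the five fitted year-sites — low values mean stable genotypes. The
heritability is the Cullis generalized form from BLUP prediction-error
variances; its high value reflects the four-replicate design and moderate
plot noise. The OP–truth correlation shows the pipeline recovering the
simulated overall performance.

Prediction and selection follow the same pattern (`preprocess_features()`,
`cv_scheme()`, `cross_validate()`, `feature_importance()`,
`efficiency_analysis()`); `vignettes/phenomic-met-analysis.Rmd` documents
the models, the defaults and their rationale. A thin command-line wrapper
for the main steps is installed at `inst/cli/phenomet.R`.

## Tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "phenomet",
                               load_package = "installed")'
```

The suite covers each module against independent oracles (ANOVA closed
forms, dense-matrix likelihood and PEV computations, SVD constructions,
enumeration on toys, an independent PLS implementation) plus
property-style invariance checks, and a statistical acceptance file that
re-runs the estimators at study scale.

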