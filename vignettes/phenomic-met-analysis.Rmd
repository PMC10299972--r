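---
title: "Two-stage factor-analytic MET analysis and phenomic selection with phenomet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage factor-analytic MET analysis and phenomic selection with phenomet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Early-generation wheat breeding decisions are taken on small, unreplicated
plots where yield cannot be measured reliably. Phenomic selection (PS)
replaces the missing target-trait measurement with predictions from
intermediate high-throughput field phenotyping (HTFP) traits — dose-response
curve parameters of stem elongation (category C), timing of key stages
(category T) and quantities at defined time points (category Q), all derived
from drone imagery. The premise that makes this work is statistical:
genotype-by-environment (G×E) interactions of the intermediate traits are
less complex than those of the target traits, so a predictor trained on a
small multi-environment trial (MET) transfers to a new environment.

`phenomet` implements the full analysis chain needed to test and exploit
that premise: a weighted two-stage mixed-model analysis of MET plot data,
factor-analytic (FA) G×E modelling with model selection, the FAST dissection
of an FA fit into overall performance (OP) and stability (RMSD), phenomic
prediction with partial least squares (PLS) and random forests (RF) under
unseen-genotype/unseen-environment cross-validation, and a
selection-efficiency evaluation of an OP threshold on top of breeders'
decisions. A synthetic MET generator with known ground truth makes every
stage testable.

## Stage 1: per-year-site spatial analysis

For one year-site and trait, plot values $\hat\theta_{jk}$ follow

$$\hat\theta_{jk} = \theta_{ij} + f(x_{jk}, y_{jk}) + p_{r(jk)} + p_{c(jk)} + e_{jk},
\qquad \mathrm{var}(e) = \sigma^2 w^{-1},$$

with genotype effects $\theta_{ij}$ (fixed for BLUEs, random for
repeatability), a smooth bivariate surface $f$, random row and column
effects, and weights $w = 1/\mathrm{SE}^2$ from the reported standard errors
of the upstream dynamic modelling. The surface is a tensor-product cubic
B-spline with second-order difference penalties, converted to mixed-model
form by eigen-decomposition of the combined penalty: the penalty null space
(bilinear in $x$, $y$) enters the fixed effects, the penalized part becomes
an i.i.d. random basis whose variance is the inverse smoothing parameter.
Knots are placed roughly one per two rows/columns, capped at 20 segments per
direction. This is the same model class as the PS-ANOVA spatial engines used
for field trials; since stage 2 consumes only BLUEs and their standard
errors, residual differences between spline flavours are absorbed by the
stage-2 weights.

Stage-1 SEs are taken from the diagonal of the fixed-effect
variance-covariance matrix (the pairwise-contrast alternative is not
implemented); stage-2 weights are $1/\mathrm{SE}^2$. Traits measured only at
genotype level (grain protein from merged probes) skip stage 1 and enter
stage 2 with unit weights.

Repeatability (within-year-site generalized heritability) follows the
Oakey construction from the genotype prediction-error-variance (PEV)
matrix. Two variants exist in the literature; the mean-PEV form
$1 - \mathrm{tr}(C_{gg})/(m\hat\sigma^2_g)$ retains the direction of the
genotype space that is confounded with the trial mean, whose PEV equals the
prior variance and which therefore drags the estimate down (on a balanced
toy with $\sigma^2_g = 15$, $\sigma^2_e = 2$, $r = 2$ it yields 0.625 where
the plot-basis value is $15/16 = 0.9375$). The default is therefore the
eigenvalue form — the mean of $1 - \lambda_i$ over the $m-1$ smallest
eigenvalues of $C_{gg}/\hat\sigma^2_g$ — which reproduces the plot-basis
formula on balanced designs; `method = "mean_pev"` exposes the other
variant.

## Stage 2: across-year-site models

Adjusted means $\hat\theta_{ij}$ are modelled as

$$\hat\theta_{ij} = \mu + u_j + \theta_i + (\theta u)_{ij} + e_{ij},
\qquad \mathrm{var}(e) = \sigma^2 w^{-1},$$

with fixed year-site means, random genotype main effects and random
interactions with uniform (`Id`) or per-year-site (`Diag`) variance. The
factor-analytic extension replaces $\theta_i + (\theta u)_{ij}$ by
environment loadings times genotype scores plus a `Diag` lack-of-fit,
giving the G×E covariance $\Lambda\Lambda' + \mathrm{diag}(\Psi)$ across
year-sites. With five year-sites at most two factors are identifiable
(parameter count of the FA structure must not exceed the unstructured
covariance); the first-factor-only loading constraint (upper triangle of
$\Lambda$ fixed at zero) identifies the rotation, which is irrelevant after
the FAST rotation below.

Implementation notes, in decreasing order of consequence:

* **Confounded lack-of-fit.** With one observation per genotype × year-site
  cell, the `Diag` lack-of-fit and the weighted residual are confounded in
  the likelihood; they are separable only through the weight heterogeneity
  ($\psi_j$ is constant per year-site, $\sigma^2/w$ varies per cell). The
  engine folds the lack-of-fit into a diagonal residual
  $\sigma^2/w + \psi_j$, which leaves the likelihood identical and shrinks
  the mixed-model equations by one effect per cell; lack-of-fit BLUPs are
  recovered afterwards by shrinking the cell residuals with
  $\psi_j/(\psi_j + \sigma^2/w)$.
* **Non-negative `Diag` variances.** Interaction variances are parameterized
  on the log scale and are therefore non-negative. Unconstrained REML can
  produce negative `Diag` estimates; allowing them would make the implied
  covariance indefinite and unusable downstream, so the non-negative
  parameterization is used throughout and near-zero estimates sit at a
  `1e-8` floor.
* **Residual scale.** The stage-2 residual $\sigma^2$ multiplying $w^{-1}$
  is freely estimated by default (it calibrates optimistic or pessimistic
  stage-1 SEs); `sigma2_fixed = 1` restores the convention of trusting the
  stage-1 SEs exactly.
* **Restricted likelihood.** All models are fitted by REML through the
  sparse Cholesky factor of the mixed-model coefficient matrix, using the
  identity $\log|V| + \log|X'V^{-1}X| = \log|R| + \log|G| + \log|C|$.
  Variance parameters are optimized by L-BFGS-B on transformed scales
  (log variances, log-Cholesky for 2×2 blocks, raw loadings) with
  scale-aware box bounds, a forward-difference gradient during the search
  and a central-difference polish at the end (the polish is what brings
  balanced-design estimates to within $10^{-6}$ of the ANOVA closed forms).
  Convergence is declared by the optimizer's relative-change and projected
  -gradient criteria (about $2\times10^{-9}$ and $10^{-5}$); a stop at the
  iteration cap triggers up to two restarts with fresh quasi-Newton memory
  before the fit is flagged unconverged.

Heritability across year-sites is the Cullis form
$H^2 = 1 - \bar v_\Delta / (2\hat\sigma^2_g)$ with $\bar v_\Delta$ the mean
PEV of pairwise genotype-BLUP differences (pairwise differences cancel the
mean-confounded direction, so no eigenvalue trimming is needed here).

Genetic correlations come from the bivariate extension: per-trait fixed
year-site means, an unstructured 2×2 genotype covariance, and — because
interaction and residual are confounded with one observation per cell and
trait — a single unstructured 2×2 covariance per cell for their sum.
Traits are standardized internally; moment-based warm starts (genotype-mean
covariance and within-cell residual covariance) make the near-singular
self-correlation case converge cleanly.

## Model selection and trait screening

Four candidates (`Id`, `Diag`, `FA1`, `FA2`) are compared by BIC computed
from the full log-likelihood: the restricted log-likelihood plus the
fixed-effect profile term $\tfrac12\log|X'V^{-1}X| - \tfrac{p}{2}\log 2\pi$,
so models with different fixed effects remain comparable. The parameter
count is the number of estimated variance parameters plus fixed
coefficients, and the BIC sample size is the number of observations (the
"effective sample size" refinements in the literature are not printed
anywhere to calibrate against, so the plain $n$ is used and documented
here). Only model ranking is considered reproducible; BIC magnitudes depend
on likelihood constants.

The screening rule distinguishes roles. Intermediate traits whose best
model is factor-analytic show complex G×E and are flagged for discarding
(with propagation: a trait derived from a discarded trait is discarded
too). For target traits discarding is not an option; `Id` is kept when it
is BIC-minimal, otherwise `FA2` is preferred because it supports the
OP/RMSD dissection. A crossover flag records mixed signs in the rotated
first-factor loadings.

## FAST: overall performance and stability

`rotate_loadings()` rotates an FA fit to principal axes
($\Lambda'\Lambda$ diagonal, non-increasing, first-factor loading sum
positive) and counter-rotates the scores so fitted G×E effects are
unchanged. Then

$$\mathrm{OP}_i = \bar\lambda_1 f_{i1}, \qquad
\mathrm{RMSD}_i = \sqrt{\tfrac1p \sum_j \big(\textstyle\sum_{h\ge2}
\lambda_{jh} f_{ih}\big)^2}.$$

By default OP is re-centered by the mean fixed year-site intercept so it
lives on the trait scale (t/ha for yield); `include_mean = FALSE` gives the
deviation form. RMSD averages over the fitted population of environments —
no extrapolation to unseen ones. With a single factor RMSD is identically
zero; low RMSD means high stability.

## Phenomic prediction

Feature tables carry one row per genotype (× year-site) with up to eleven
intermediate-trait columns. Preprocessing removes rows whose dose-response
parameters are missing (upstream curve fits that failed to converge), drops
the implausible tiller-count outlier rule for the yield task
(`n_tiller > 8000`), and maps the five-level breeder decision scale
(selected, sister selected, repeated, sister repeated, discarded) to the
ordinal values 3, 2, 1, 0, −1, treated as a regression response.

Cross-validation schemes mirror the breeding question: `unseen_E` leaves
one year-site out, `unseen_G` one genotype, `unseen_GE` builds one fold per
observed cell whose training set excludes the whole year-site *and* the
whole genotype (each fold carries an assertion to that effect), and
`kfold` is repeated stratified k-fold (stratified by year-site; 8 folds and
5 repeats by default — the repeat count is a package choice, seeded).
On the 45-genotype / 5-year-site / 36-per-site layout these yield exactly
5, 45 and 179 folds.

PLS1 (NIPALS) is implemented in the package — predictors standardized
within each training fold, response centered — because no PLS implementation
is otherwise available to the package's dependencies; an independent
implementation (mixOmics) serves as a cross-check in the test suite. The
number of components is tuned once per task by ten-fold CV over all rows.
RF uses `ranger`; its grid (trees in {100, 250, 500, 750, 1000}, `mtry` in
1..11 — the grid discretization of the tree count is a package choice within
the stated bounds) is tuned per outer fold by inner ten-fold CV
(leave-one-out for `unseen_GE`). Metrics are RMSE, nRMSE
($100\cdot\mathrm{RMSE}/\overline{y}$ — the mean normalizer reproduces the
printed pairs such as RMSE 1.23 t/ha ↔ nRMSE 20.8% at mean 5.913 t/ha) and
Spearman's $r_s$ on pooled out-of-fold predictions.

Feature importance: for PLS the signed coefficients on standardized
predictors (the summary of loading weights over all components; sign
convention tested on constructed responses) with jackknife 95% intervals;
for RF the mean increase in out-of-bag MSE over 50 permutation runs per
feature with interval from the runs.

## Selection efficiency

`efficiency_analysis()` compares the breeders' selection with an enhanced
selection that drops lines predicted below an OP threshold. A selected line
counts as a success when its observed performance (e.g. next-generation
yield) reaches the threshold; efficiency is successes over selected lines,
and the denominator over all candidate lines is reported alongside because
the verbal definition admits both. `threshold = "optimize"` maximizes the
efficiency *increase* (enhanced minus baseline): the enhanced efficiency
alone is degenerate — any threshold below all predictions scores 1 — whereas
the increase has an interior maximum, matching the retrospective
threshold-curve evaluation on an already-grown generation. Ties resolve to
the lower threshold; lines excluded despite observed performance above the
threshold are counted as false exclusions.

## The synthetic MET generator

`sim_config()` defaults emulate the study conditions: 45 elite winter-wheat
genotypes, five year-sites (two years × three sites), four replicates
(three in one year-site), and 20% of genotypes absent per year-site —
whole genotype × year-site cells dropped, reproducing the unbalancedness of
a variety-testing series where the sets differ between years. Yield is
generated as year-site mean (4.9–7.5 t/ha, trait mean ≈ 5.9 t/ha) +
genotype main effect ($\sigma^2_g = 0.35$) + two-factor FA G×E
(first-factor loadings ≈ 0.4–0.6, mild second factor, specific variances
0.05) + a smooth spatial surface (random low-order sinusoid products scaled
to $\sigma^2_{sp} = 0.2$ — the sinusoid basis commits to no particular
spline family) + row/column effects + plot noise. Reported SEs are
$\sqrt{\sigma^2_e}$ times a per-plot lognormal factor (sd 0.25 on the log
scale) so the weighting path is genuinely exercised; the SE magnitude is a
free parameter of the generator since no empirical values are available to
copy. Eleven secondary traits are linear in the genotype main effect with
independent genetic and plot noise; grain protein is linked negatively
(−0.8% per t/ha) and generated at genotype × year-site level with unit
weights. Breeder decisions threshold a standardized latent index
(true OP − ½·true RMSD + noise) at 1.5/1.0/0.5/0.

What the generator does *not* emulate: spatially correlated residuals
beyond the smooth trend, non-Gaussian errors, genotype-specific SE
patterns, trait time-series (traits are generated directly at the
intermediate level), and any genetic relatedness structure among
genotypes. Passing recovery tests on this generator therefore shows the
estimators are correct under the stated model, not that the model captures
every feature of real field data.

One estimand subtlety: the FA model has no separate genotype main-effect
term, so its fitted covariance estimates
$\sigma^2_g J + \Lambda\Lambda' + \mathrm{diag}(\Psi)$ when a main effect is
simulated. Parameter-recovery studies therefore set $\sigma^2_g = 0$ so the
estimand is exactly $\Lambda\Lambda' + \mathrm{diag}(\Psi)$.

## Problem sizes and runtime choices

The statistical acceptance checks run at: 20 random balanced designs for
the ANOVA-oracle equivalence; 200 genotypes × 5 year-sites × 20 seeds for
FA recovery; 100 genotypes × 20 seeds per scenario for model-selection
power (power at this size exceeds 90% for both the no-G×E and the
strong-two-factor scenario); 500 genotypes × 20 seeds per value for genetic
-correlation bias; 200 genotypes for Cullis-H² recovery against a dense PEV
oracle and 40 genotypes × 4 replicates for the Oakey plot-basis check.
These sizes are chosen so the full suite completes on a single core in
well under half an hour while keeping Monte-Carlo error far below the
tolerances tested.

## Known limitations

* No autoregressive or other correlated residual structures in stage 1;
  no one-stage joint analysis (the two-stage route is the design).
* At most two FA factors; no Finlay–Wilkinson or AMMI stability measures.
* The bivariate model handles exactly two traits and complete cells.
* The REML engine targets trial-sized problems (thousands of observations),
  not national multi-million-plot evaluations.
* No genomic information anywhere — this is phenomic selection by design.
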