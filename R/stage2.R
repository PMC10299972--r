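# Stage 2: across-year-site analysis of weighted genotype BLUEs.
#
# Overall genotype means with Id/Diag interaction variance, generalized
# heritability (Cullis), bivariate genetic correlations, factor-analytic
# (reduced-rank + Diag) GxE models, BIC model selection and the
# trait-screening rule for intermediate HTFP traits.

check_means <- function(means) {
  req <- c("year_site", "genotype", "blue", "weight")
  if (!all(req %in% names(means))) {
    stop("adjusted means need columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(means[, c("year_site", "genotype")])) {
    stop("more than one row per (year_site, genotype)")
  }
  if (any(means$weight <= 0)) stop("weights must be positive")
  means$year_site <- factor(means$year_site)
  means$genotype <- factor(means$genotype)
  means
}

#' Fit the overall (stage-2) genotype-means model
#'
#' Across-year-site weighted mixed model for adjusted genotype means:
#' fixed global intercept and year-site effects, random genotype main
#' effects, random genotype-by-year-site interactions with uniform
#' (`"Id"`) or per-year-site heterogeneous (`"Diag"`) variance, and
#' residuals `var(e) = sigma2 / w` with the stage-1 weights.
#'
#' @param means `AdjustedMeans` data.frame (`year_site`, `genotype`,
#'   `blue`, `weight`, optionally `trait`, `se`).
#' @param gxe Interaction variance structure, `"Id"` or `"Diag"`.
#' @param sigma2_fixed Optionally fix the stage-2 residual variance
#'   (e.g. 1, the common two-stage convention); default estimates it.
#' @return A `reml_fit` with random terms `genotype` and `gxe`, plus
#'   attributes `gxe` and `trait`.
#' @export
fit_overall <- function(means, gxe = c("Id", "Diag"), sigma2_fixed = NULL) {
  gxe <- match.arg(gxe)
  means <- check_means(means)
  p <- nlevels(means$year_site)
  if (p < 2) stop("need at least 2 year-sites (interaction inestimable)")
  X <- stats::model.matrix(~ year_site, means)
  # with one observation per cell the interaction is confounded with the
  # residual; fold it into a per-year-site diagonal residual component
  # (identical likelihood, much smaller mixed-model equations)
  res_outer <- if (gxe == "Id") factor(rep("all", nrow(means))) else means$year_site
  fit <- reml_fit(means$blue, X,
                  list(ranef("genotype", vs_id(), inner = means$genotype)),
                  weights = means$weight,
                  residual = list(kind = "weighted_diag", outer = res_outer),
                  sigma2_fixed = sigma2_fixed)
  # recover interaction BLUPs: E[(theta u)_ij | y] shrinks the cell
  # residual by psi / (psi + sigma2 / w)
  psi <- fit$vp$residual$psi[as.integer(res_outer)]
  rvar <- fit$vp$residual$var_obs
  resid <- means$blue - as.vector(X %*% fit$beta) -
    fit$blup$genotype[as.character(means$genotype)]
  iblup <- matrix(NA_real_, nlevels(means$genotype), p,
                  dimnames = list(levels(means$genotype), levels(means$year_site)))
  iblup[cbind(as.integer(means$genotype), as.integer(means$year_site))] <-
    psi / rvar * resid
  fit$blup$gxe <- iblup
  fit$vp$gxe <- list(sigma2 = stats::setNames(as.numeric(fit$vp$residual$psi),
                                              levels(res_outer)))
  fit$gxe <- gxe
  fit$trait <- if ("trait" %in% names(means)) as.character(means$trait[1]) else NA_character_
  fit
}

#' Across-year-site heritability (Cullis form)
#'
#' `H2 = 1 - vbar_delta / (2 sigma2_g)` where `vbar_delta` is the mean
#' prediction-error variance of pairwise genotype BLUP differences.
#'
#' @param fit A genotype-random `reml_fit` (e.g. from [fit_overall()]).
#' @return Heritability in \[0, 1\].
#' @export
heritability_cullis <- function(fit) {
  stopifnot(inherits(fit, "reml_fit"))
  s2g <- fit$vp$genotype$sigma2
  if (is.null(s2g)) stop("fit has no random 'genotype' term")
  if (s2g < 1e-7) return(0)
  P <- fit$pev("genotype")
  m <- nrow(P)
  vbar <- (2 * m * sum(diag(P)) - 2 * sum(P)) / (m * (m - 1))
  min(max(1 - vbar / (2 * s2g), 0), 1)
}

#' Genetic correlation between two traits (bivariate model)
#'
#' Extends the overall-means model to two traits on their shared
#' (year-site, genotype) cells: fixed per-trait intercepts and year-site
#' effects, an unstructured 2x2 genotype covariance, and an unstructured
#' 2x2 combined interaction-plus-residual covariance per cell (the two
#' terms are confounded with one observation per cell and trait). The
#' genetic correlation is
#' `r_g = Cov(g_t1, g_t2) / sqrt(Var(g_t1) Var(g_t2))`.
#'
#' Traits are internally standardized to unit variance for numerical
#' stability; `r_g` is invariant to the scaling, reported components are
#' back-transformed.
#'
#' @param means_t1,means_t2 `AdjustedMeans` data.frames for the two traits.
#' @return List: `r_g` (NA with `reason` when a genetic variance
#'   vanishes), `genetic_cov` and `residual_cov` (2x2 matrices on the
#'   original trait scales), `n_genotypes`, `n_cells`, `converged`.
#' @export
genetic_correlation <- function(means_t1, means_t2) {
  m1 <- check_means(means_t1); m2 <- check_means(means_t2)
  key <- c("year_site", "genotype")
  mm <- merge(m1[, c(key, "blue")], m2[, c(key, "blue")],
              by = key, suffixes = c("_t1", "_t2"))
  mm <- mm[stats::complete.cases(mm), ]
  mm$year_site <- droplevels(factor(mm$year_site))
  mm$genotype <- droplevels(factor(mm$genotype))
  if (nlevels(mm$year_site) < 2 || nlevels(mm$genotype) < 3) {
    stop("traits must share at least 2 year-sites and 3 genotypes")
  }
  s1 <- stats::sd(mm$blue_t1); s2 <- stats::sd(mm$blue_t2)
  if (s1 == 0 || s2 == 0) stop("degenerate trait with zero variance")
  long <- data.frame(
    y = c(mm$blue_t1 / s1, mm$blue_t2 / s2),
    trait = factor(rep(c("t1", "t2"), each = nrow(mm))),
    year_site = rep(mm$year_site, 2),
    genotype = rep(mm$genotype, 2),
    cell = rep(interaction(mm$genotype, mm$year_site, drop = TRUE), 2))
  X <- stats::model.matrix(~ trait * year_site, long)
  terms <- list(ranef("genotype", vs_us2(),
                      inner = long$genotype, outer = long$trait))
  # moment-based warm starts: genotype-mean covariance for the genetic
  # block, within-cell residual covariance for the combined term
  y1 <- mm$blue_t1 / s1; y2 <- mm$blue_t2 / s2
  e1 <- stats::resid(stats::lm(y1 ~ mm$year_site + mm$genotype))
  e2 <- stats::resid(stats::lm(y2 ~ mm$year_site + mm$genotype))
  Se0 <- stats::cov(cbind(e1, e2)) * (nrow(mm) - 1) /
    max(nrow(mm) - nlevels(mm$year_site) - nlevels(mm$genotype) + 1, 1)
  gm <- cbind(tapply(y1, mm$genotype, mean), tapply(y2, mm$genotype, mean))
  Sg0 <- stats::cov(gm) - Se0 / nlevels(mm$year_site)
  us2_start <- function(S) {
    S <- S + diag(2) * max(1e-4, 1e-3 * mean(diag(S)))
    ev <- eigen(S, symmetric = TRUE)
    S <- ev$vectors %*% diag(pmax(ev$values, 1e-4)) %*% t(ev$vectors)
    L <- t(chol(S))
    c(log(L[1, 1]), L[2, 1], log(L[2, 2]))
  }
  fit <- reml_fit(long$y, X, terms,
                  residual = list(kind = "us2", group = long$cell,
                                  slot = as.integer(long$trait)),
                  start = list(genotype = us2_start(Sg0),
                               residual = us2_start(Se0)))
  Sg <- fit$vp$genotype$cov
  Se <- fit$vp$residual$cov
  scale_back <- function(S) S * tcrossprod(c(s1, s2))
  v1 <- Sg[1, 1]; v2 <- Sg[2, 2]
  if (v1 < 1e-6 || v2 < 1e-6) {
    return(list(r_g = NA_real_, reason = "genetic variance near zero",
                genetic_cov = scale_back(Sg), residual_cov = scale_back(Se),
                n_genotypes = nlevels(mm$genotype), n_cells = nrow(mm),
                converged = fit$converged))
  }
  r_g <- Sg[1, 2] / sqrt(v1 * v2)
  list(r_g = max(min(r_g, 1), -1), reason = NULL,
       genetic_cov = scale_back(Sg), residual_cov = scale_back(Se),
       n_genotypes = nlevels(mm$genotype), n_cells = nrow(mm),
       converged = fit$converged)
}

#' Fit a factor-analytic (reduced-rank + Diag) GxE model
#'
#' Stage-2 model where the genotype-by-year-site effects carry a
#' factor-analytic covariance `Lambda Lambda' + diag(Psi)` across
#' year-sites: a reduced-rank term (environment loadings x genotype
#' scores) plus heterogeneous lack-of-fit variances, with weighted
#' residuals. Warm starts come from the eigen-decomposition of the
#' sample environment covariance of genotype means.
#'
#' @param means `AdjustedMeans` data.frame.
#' @param n_factors Number of factors (1 or 2 with 5 year-sites).
#' @param sigma2_fixed Optionally fix the stage-2 residual variance.
#' @return Object of class `"fa_fit"`: `loadings` (p x k),
#'   `specific_vars` (Psi), `scores` (genotype BLUPs, m x k), `delta`
#'   (lack-of-fit BLUPs), `env_intercepts` (mu + u_j), the underlying
#'   `fit`, and `rotated = FALSE`.
#' @export
fit_fa <- function(means, n_factors, sigma2_fixed = NULL) {
  means <- check_means(means)
  p <- nlevels(means$year_site)
  k <- as.integer(n_factors)
  if (p < k + 1L) stop("need at least n_factors + 1 year-sites")
  invisible(vs_rr_diag(p, k)) # identifiability check (errors when violated)
  X <- stats::model.matrix(~ year_site, means)

  # warm start from the sample covariance of centered cell values
  M <- matrix(NA_real_, nlevels(means$genotype), p,
              dimnames = list(levels(means$genotype), levels(means$year_site)))
  M[cbind(as.integer(means$genotype), as.integer(means$year_site))] <- means$blue
  M <- sweep(M, 2, colMeans(M, na.rm = TRUE))
  S <- stats::cov(M, use = "pairwise.complete.obs")
  S[!is.finite(S)] <- 0
  es <- eigen((S + t(S)) / 2, symmetric = TRUE)
  ev <- pmax(es$values[seq_len(k)], 1e-4)
  L0 <- es$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(ev), k, k)
  if (k == 2) { # rotate start so the structural zero Lambda[1,2] holds
    phi <- atan2(L0[1, 2], L0[1, 1])
    G <- matrix(c(cos(phi), -sin(phi), sin(phi), cos(phi)), 2, 2)
    L0 <- L0 %*% G
  }
  psi0 <- pmax(0.1 * diag(S), 1e-4)
  start <- list(gxe = L0[lambda_free_idx(p, k)],
                residual = c(log(psi0), if (is.null(sigma2_fixed)) 0))

  # lack-of-fit Diag is confounded with the residual (one observation per
  # cell): fold it into a per-year-site diagonal residual component; the
  # likelihood is identical and the equations much smaller
  fit <- reml_fit(means$blue, X,
                  list(ranef("gxe", vs_rr(p, k), inner = means$genotype,
                             outer = means$year_site)),
                  weights = means$weight,
                  residual = list(kind = "weighted_diag",
                                  outer = means$year_site),
                  sigma2_fixed = sigma2_fixed, start = start)
  beta <- fit$beta
  env_int <- beta[1] + c(0, beta[-1])
  names(env_int) <- levels(means$year_site)
  # recover lack-of-fit BLUPs from the shrunken cell residuals
  psi_hat <- fit$vp$residual$psi
  rvar <- fit$vp$residual$var_obs
  resid <- means$blue - as.vector(X %*% fit$beta) -
    rowSums(fit$blup$gxe$scores[as.character(means$genotype), , drop = FALSE] *
              fit$vp$gxe$loadings[as.integer(means$year_site), , drop = FALSE])
  delta <- matrix(NA_real_, nlevels(means$genotype), p,
                  dimnames = list(levels(means$genotype), levels(means$year_site)))
  delta[cbind(as.integer(means$genotype), as.integer(means$year_site))] <-
    psi_hat[as.integer(means$year_site)] / rvar * resid
  out <- list(loadings = fit$vp$gxe$loadings,
              specific_vars = stats::setNames(as.numeric(psi_hat),
                                              levels(means$year_site)),
              scores = fit$blup$gxe$scores,
              delta = delta,
              env_intercepts = env_int,
              n_factors = k, year_sites = levels(means$year_site),
              genotypes = levels(means$genotype),
              trait = if ("trait" %in% names(means)) as.character(means$trait[1]) else NA_character_,
              fit = fit, converged = fit$converged, rotated = FALSE)
  rownames(out$loadings) <- levels(means$year_site)
  class(out) <- "fa_fit"
  out
}

#' Environment correlation matrix implied by a factor-analytic fit
#'
#' `C = D^-1/2 (Lambda Lambda' + diag(Psi)) D^-1/2` with `D` the
#' diagonal of the implied GxE covariance: the estimated genetic
#' correlations between year-sites for common GxE effects.
#'
#' @param fa A `"fa_fit"`.
#' @return p x p correlation matrix with unit diagonal.
#' @export
env_correlations <- function(fa) {
  stopifnot(inherits(fa, "fa_fit"))
  if (!isTRUE(fa$converged)) warning("correlations from an unconverged FA fit")
  G <- tcrossprod(fa$loadings) + diag(fa$specific_vars, nrow(fa$loadings))
  d <- diag(G)
  if (any(d <= 0)) stop("zero diagonal entry in implied GxE covariance")
  C <- stats::cov2cor(G)
  dimnames(C) <- list(fa$year_sites, fa$year_sites)
  C
}

#' Select the GxE model for a trait by BIC
#'
#' Fits the four candidate stage-2 models (`Id`, `Diag`, `FA1`, `FA2`),
#' compares full-likelihood BICs among converged fits, and applies the
#' screening rule: intermediate traits whose best model is
#' factor-analytic (complex GxE) are flagged for discarding; for target
#' traits the `Id` model is kept when minimal, otherwise `FA2` is
#' preferred (it allows the dissection into overall performance and
#' stability). A crossover flag records mixed-sign first-factor loadings
#' of the best factor-analytic model.
#'
#' @param means `AdjustedMeans` data.frame.
#' @param role `"intermediate"` or `"target"`.
#' @param trait Optional trait label (defaults to the `trait` column).
#' @return Object of class `"gxe_report"`: `candidates` (data.frame of
#'   bic / loglik_full / converged), `selected`, `crossover`,
#'   `discarded`, `reason`, plus the fitted objects in `fits`.
#' @export
select_gxe_model <- function(means, role = c("intermediate", "target"),
                             trait = NULL) {
  role <- match.arg(role)
  means <- check_means(means)
  if (is.null(trait)) {
    trait <- if ("trait" %in% names(means)) as.character(means$trait[1]) else NA_character_
  }
  fits <- list(
    Id = tryCatch(fit_overall(means, "Id"), error = function(e) NULL),
    Diag = tryCatch(fit_overall(means, "Diag"), error = function(e) NULL),
    FA1 = tryCatch(fit_fa(means, 1), error = function(e) NULL),
    FA2 = tryCatch(fit_fa(means, 2), error = function(e) NULL))
  getfit <- function(f) if (inherits(f, "fa_fit")) f$fit else f
  cand <- do.call(rbind, lapply(names(fits), function(nm) {
    f <- getfit(fits[[nm]])
    data.frame(model = nm,
               bic = if (is.null(f)) NA_real_ else f$bic,
               loglik_full = if (is.null(f)) NA_real_ else f$loglik_full,
               converged = if (is.null(f)) FALSE else f$converged,
               stringsAsFactors = FALSE)
  }))
  ok <- cand$converged & is.finite(cand$bic)
  if (!any(ok)) stop("no candidate GxE model converged")
  best <- cand$model[ok][which.min(cand$bic[ok])]

  crossover <- FALSE
  fa_best <- if (best %in% c("FA1", "FA2")) best else if (cand$converged[cand$model == "FA2"]) "FA2" else NULL
  if (best %in% c("FA1", "FA2")) {
    l1 <- rotate_loadings(fits[[best]])$loadings[, 1]
    crossover <- any(l1 > 1e-6) && any(l1 < -1e-6)
  }

  discarded <- FALSE; reason <- NULL; selected <- best
  if (role == "intermediate") {
    if (best %in% c("FA1", "FA2")) {
      discarded <- TRUE
      reason <- paste0("complex GxE interactions (", best, " selected by BIC)")
    }
  } else {
    if (best != "Id") {
      selected <- if (cand$converged[cand$model == "FA2"]) "FA2" else best
    }
  }
  structure(list(trait = trait, candidates = cand, selected = selected,
                 best_bic = best, crossover = crossover,
                 discarded = discarded, reason = reason, fits = fits),
            class = "gxe_report")
}

#' @export
print.gxe_report <- function(x, ...) {
  cat("GxE model report for trait:", x$trait, "\n")
  print(x$candidates, row.names = FALSE)
  cat("selected:", x$selected,
      if (x$crossover) "(crossover loadings)" else "", "\n")
  if (x$discarded) cat("DISCARDED:", x$reason, "\n")
  invisible(x)
}

#' Screen intermediate traits by GxE complexity
#'
#' A trait is discarded when its own model-selection report flags it or
#' when any trait it is derived from (its ancestors in `derivations`) is
#' discarded; reasons propagate.
#'
#' @param reports Named list of `"gxe_report"` objects (one per trait).
#' @param derivations Named character vector mapping a derived trait to
#'   its parent trait (may be empty).
#' @return List with `kept` (character vector) and `discarded`
#'   (data.frame: trait, reason).
#' @export
screen_intermediate_traits <- function(reports, derivations = character()) {
  traits <- names(reports)
  parent <- function(tr) {
    if (tr %in% names(derivations)) unname(derivations[[tr]]) else NA_character_
  }
  # cycle check
  for (tr in traits) {
    seen <- character(); cur <- tr
    while (!is.na(cur <- parent(cur))) {
      if (cur %in% c(seen, tr)) stop("cycle in trait derivations at '", tr, "'")
      seen <- c(seen, cur)
    }
  }
  own <- vapply(reports, function(r) isTRUE(r$discarded), TRUE)
  reason <- vapply(reports, function(r) {
    if (isTRUE(r$discarded)) r$reason else NA_character_
  }, "")
  disc <- own
  rsn <- reason
  changed <- TRUE
  while (changed) {
    changed <- FALSE
    for (tr in traits) {
      pa <- parent(tr)
      if (!disc[tr] && !is.na(pa) && isTRUE(disc[pa])) {
        disc[tr] <- TRUE
        rsn[tr] <- paste0("ancestor trait '", pa, "' discarded")
        changed <- TRUE
      }
    }
  }
  list(kept = traits[!disc],
       discarded = data.frame(trait = traits[disc],
                              reason = unname(rsn[disc]),
                              stringsAsFactors = FALSE))
}
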