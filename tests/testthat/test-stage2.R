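test_that("identical year-sites leave no interaction variance", {
  set.seed(1)
  m <- 40
  blues <- rnorm(m, 6, 0.6)
  means <- data.frame(year_site = rep(c("A", "B"), each = m),
                      genotype = rep(sprintf("G%02d", 1:m), 2),
                      blue = rep(blues, 2),
                      weight = rep(runif(m, 0.5, 2), 2))
  fit <- fit_overall(means, "Id")
  expect_lt(fit$vp$gxe$sigma2, 1e-4)
  expect_lt(fit$vp$residual$sigma2, 1e-4)
})

test_that("a single year-site is rejected", {
  means <- data.frame(year_site = "A", genotype = sprintf("G%02d", 1:10),
                      blue = rnorm(10), weight = 1)
  expect_error(fit_overall(means, "Id"), "2 year-sites")
})

test_that("Diag interaction variances are recovered within a factor of two", {
  cfg <- sim_config(n_genotypes = 200, sigma2_g = 1,
                    loadings_true = matrix(0, 2, 1), psi_true = c(1, 4),
                    missing_pattern = 0, seed = 21,
                    year_sites = default_year_sites(200, 0)[1:2])
  am <- simulate_adjusted_means(cfg, se_mean = 0.2)
  fit <- fit_overall(am$means, "Diag")
  psi <- fit$vp$gxe$sigma2
  expect_equal(unname(psi[2] / psi[1]), 4, tolerance = 1)
  expect_true(all(psi > 0.5 & psi < 8))
})

test_that("genotype BLUP ranking equals the mean ranking without GxE", {
  cfg <- sim_config(n_genotypes = 50, sigma2_g = 0.5,
                    loadings_true = matrix(0, 5, 2), psi_true = rep(0, 5),
                    se_lognormal_sd = 0, missing_pattern = 0, seed = 5)
  am <- simulate_adjusted_means(cfg, se_mean = 0.15)
  fit <- fit_overall(am$means, "Id")
  gm <- tapply(am$means$blue - ave(am$means$blue, am$means$year_site),
               am$means$genotype, mean)
  expect_identical(order(fit$blup$genotype[names(gm)]), order(gm))
  # interaction BLUPs are populated per cell
  expect_identical(dim(fit$blup$gxe), c(50L, 5L))
})

test_that("Cullis heritability responds to information and vanishes at null", {
  cfg <- sim_config(n_genotypes = 60, sigma2_g = 0.4, missing_pattern = 0,
                    seed = 8)
  am <- simulate_adjusted_means(cfg)
  f1 <- fit_overall(am$means, "Id")
  h1 <- heritability_cullis(f1)
  expect_true(h1 > 0 && h1 <= 1)
  # doubling every weight (twice the information per cell) raises H2
  m2 <- am$means
  m2$weight <- m2$weight * 4
  h2 <- heritability_cullis(fit_overall(m2, "Id"))
  expect_gt(h2, h1)
  # no genetic variance -> H2 ~ 0
  cfg0 <- sim_config(n_genotypes = 60, sigma2_g = 0,
                     loadings_true = matrix(0, 5, 2), psi_true = rep(0.2, 5),
                     missing_pattern = 0, seed = 9)
  am0 <- simulate_adjusted_means(cfg0)
  expect_lte(heritability_cullis(fit_overall(am0$means, "Id")), 0.05)
})

test_that("a trait correlates almost perfectly with its jittered copy", {
  pm <- pair_means(m = 80, p = 5, rg = 1, seed = 2, sd_e = 0.4)
  t2 <- pm$t1
  t2$blue <- t2$blue + rnorm(nrow(t2), 0, 1e-3)
  expect_gte(genetic_correlation(pm$t1, t2)$r_g, 0.99)
})

test_that("genetic correlation recovers a known value", {
  est <- sapply(1:5, function(s) {
    pm <- pair_means(m = 200, p = 5, rg = 0.6, seed = s)
    genetic_correlation(pm$t1, pm$t2)$r_g
  })
  expect_lt(abs(mean(est) - 0.6), 0.1)
})

test_that("the correlation formula is applied to the estimated components", {
  pm <- pair_means(m = 100, p = 5, rg = 0.5, seed = 4)
  gc <- genetic_correlation(pm$t1, pm$t2)
  Sg <- gc$genetic_cov
  expect_equal(gc$r_g, Sg[1, 2] / sqrt(Sg[1, 1] * Sg[2, 2]),
               tolerance = 1e-10)
})

test_that("degenerate genetic variance yields a missing correlation", {
  set.seed(3)
  m <- 30; p <- 3
  base <- expand.grid(year_site = paste0("S", 1:p),
                      genotype = sprintf("G%02d", 1:m))
  # trait 1 carries only year-site differences: zero genetic variance
  env <- c(S1 = 4, S2 = 6, S3 = 9)
  t1 <- data.frame(base, blue = env[base$year_site] +
                     rnorm(nrow(base), 0, 1e-4), weight = 1)
  t2 <- data.frame(base, blue = rnorm(m)[as.integer(base$genotype)] +
                     rnorm(nrow(base), 0, 0.2), weight = 1)
  gc <- genetic_correlation(t1, t2)
  expect_true(is.na(gc$r_g))
  expect_match(gc$reason, "variance")
})

test_that("insufficient overlap between traits is rejected", {
  t1 <- data.frame(year_site = "A", genotype = sprintf("G%d", 1:5),
                   blue = rnorm(5), weight = 1)
  expect_error(genetic_correlation(t1, t1), "share")
})

test_that("factor-analytic fits recover a rank-1 truth", {
  L <- matrix(seq(0.4, 0.8, length.out = 5), 5, 1)
  am <- fa_means(m = 200, loadings = L, psi = rep(0.1, 5), seed = 31)
  fa <- fit_fa(am$means, 1)
  expect_true(fa$converged)
  G <- tcrossprod(fa$loadings) + diag(fa$specific_vars)
  Gt <- tcrossprod(L) + diag(0.1, 5)
  expect_lt(norm(G - Gt, "F") / norm(Gt, "F"), 0.2)
  # genotype scores track the simulated truth (up to sign)
  expect_gt(abs(cor(fa$scores[, 1], am$truth$scores_true[, 1])), 0.9)
})

test_that("identifiability limits on the number of factors are enforced", {
  am <- fa_means(m = 30, loadings = matrix(0.5, 5, 1), psi = rep(0.1, 5),
                 seed = 1)
  expect_error(fit_fa(am$means, 5), "year-sites")
  expect_error(fit_fa(am$means, 4), "overparameterized")
})

test_that("model log-likelihoods respect nesting", {
  am <- fa_means(m = 100, loadings = cbind(seq(0.4, 0.6, length.out = 5),
                                           c(0.3, -0.3, 0.25, -0.25, 0.2)),
                 psi = rep(0.05, 5), sigma2_g = 0.2, seed = 13)
  fi <- fit_overall(am$means, "Id")
  fd <- fit_overall(am$means, "Diag")
  f1 <- fit_fa(am$means, 1)
  f2 <- fit_fa(am$means, 2)
  expect_true(all(c(fi$converged, fd$converged, f1$converged, f2$converged)))
  expect_lte(fi$loglik_full, fd$loglik_full + 1e-4)
  expect_lte(fd$loglik_full, f2$fit$loglik_full + 1e-4)
  expect_lte(f1$fit$loglik_full, f2$fit$loglik_full + 1e-4)
})

test_that("environment correlations are a valid correlation matrix", {
  # rank-1 with zero specific variances: all correlations are one
  stub <- fa_stub(matrix(c(0.5, 0.7, 0.9), 3, 1),
                  matrix(rnorm(30), 10, 3)[, 1, drop = FALSE])
  C1 <- env_correlations(stub)
  expect_equal(unname(C1), matrix(1, 3, 3))
  # fitted case: symmetric PSD, unit diagonal
  am <- fa_means(m = 80, loadings = cbind(seq(0.4, 0.6, length.out = 5),
                                          c(0.2, -0.2, 0.15, -0.15, 0.1)),
                 psi = rep(0.05, 5), seed = 14)
  C <- env_correlations(fit_fa(am$means, 2))
  expect_equal(diag(C), setNames(rep(1, 5), colnames(C)))
  expect_equal(C, t(C))
  expect_gte(min(eigen(C, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  expect_true(all(abs(C) <= 1 + 1e-8))
})

test_that("model selection applies the screening rules", {
  # Id truth -> Id selected for both roles
  cfg <- sim_config(n_genotypes = 100, sigma2_g = 0.35,
                    loadings_true = matrix(0, 5, 2), psi_true = rep(0, 5),
                    missing_pattern = 0, seed = 1)
  am <- simulate_adjusted_means(cfg)
  rep_t <- select_gxe_model(am$means, role = "target")
  expect_identical(rep_t$selected, "Id")
  expect_false(rep_t$discarded)
  # strong two-factor truth -> FA2 for targets, discarded for intermediates
  L <- cbind(seq(0.5, 0.7, length.out = 5), c(0.5, -0.5, 0.45, -0.45, 0.4))
  am2 <- fa_means(m = 100, loadings = L, psi = rep(0.02, 5), seed = 2,
                  se_mean = 0.15)
  rep_t2 <- select_gxe_model(am2$means, role = "target")
  expect_identical(rep_t2$selected, "FA2")
  rep_i2 <- select_gxe_model(am2$means, role = "intermediate")
  expect_true(rep_i2$discarded)
  expect_match(rep_i2$reason, "FA")
  expect_identical(rep_i2$candidates$model, c("Id", "Diag", "FA1", "FA2"))
})

test_that("discard reasons propagate through trait derivations", {
  mk <- function(discarded, reason = NULL) {
    structure(list(discarded = discarded, reason = reason),
              class = "gxe_report")
  }
  reports <- list(LA_max = mk(TRUE, "complex GxE"),
                  t_LA_max = mk(FALSE),
                  PH_max = mk(FALSE))
  out <- screen_intermediate_traits(reports,
                                    derivations = c(t_LA_max = "LA_max"))
  expect_setequal(out$kept, "PH_max")
  expect_setequal(out$discarded$trait, c("LA_max", "t_LA_max"))
  expect_match(out$discarded$reason[out$discarded$trait == "t_LA_max"],
               "ancestor")
  # no discards -> identity
  out2 <- screen_intermediate_traits(list(a = mk(FALSE), b = mk(FALSE)))
  expect_setequal(out2$kept, c("a", "b"))
  # chain of three with the middle discarded -> exactly two discarded
  reports3 <- list(a = mk(FALSE), b = mk(TRUE, "complex"), c = mk(FALSE))
  out3 <- screen_intermediate_traits(reports3, c(b = "a", c = "b"))
  expect_identical(nrow(out3$discarded), 2L)
  expect_setequal(out3$discarded$trait, c("b", "c"))
  # cycles are detected
  expect_error(screen_intermediate_traits(reports3, c(a = "c", b = "a", c = "b")),
               "cycle")
})
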