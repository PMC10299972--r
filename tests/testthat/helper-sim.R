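# shared simulation helpers for the test suite

# balanced one-way design with ANOVA closed-form oracle
one_way <- function(m, r, s2g, s2e, seed) {
  set.seed(seed)
  g <- factor(rep(seq_len(m), each = r))
  y <- rnorm(m, 0, sqrt(s2g))[as.integer(g)] + rnorm(m * r, 0, sqrt(s2e))
  msw <- sum(tapply(y, g, function(v) sum((v - mean(v))^2))) / (m * (r - 1))
  msb <- r * sum((tapply(y, g, mean) - mean(y))^2) / (m - 1)
  list(y = y, g = g, X = matrix(1, m * r, 1),
       s2e_anova = msw, s2g_anova = (msb - msw) / r)
}

# adjusted means from a pure FA(+main-effect) truth at stage-2 level
fa_means <- function(m, loadings, psi, seed, sigma2_g = 0, se_mean = 0.2,
                     missing = 0) {
  p <- nrow(as.matrix(loadings))
  cfg <- sim_config(n_genotypes = m, sigma2_g = sigma2_g,
                    loadings_true = as.matrix(loadings), psi_true = psi,
                    missing_pattern = missing, seed = seed,
                    year_sites = default_year_sites(m, missing)[seq_len(p)])
  simulate_adjusted_means(cfg, se_mean = se_mean)
}

# paired adjusted means with known genetic correlation
pair_means <- function(m, p, rg, seed, sd_e = 0.5) {
  set.seed(seed)
  g1 <- rnorm(m)
  g2 <- rg * g1 + sqrt(1 - rg^2) * rnorm(m)
  ysn <- paste0("S", seq_len(p))
  env1 <- rnorm(p, 10, 1); env2 <- rnorm(p, 5, 1)
  geno <- sprintf("G%04d", seq_len(m))
  m1 <- do.call(rbind, lapply(seq_len(p), function(j) {
    data.frame(year_site = ysn[j], genotype = geno,
               blue = env1[j] + g1 + rnorm(m, 0, sd_e), weight = 1)
  }))
  m2 <- do.call(rbind, lapply(seq_len(p), function(j) {
    data.frame(year_site = ysn[j], genotype = geno,
               blue = env2[j] + g2 + rnorm(m, 0, sd_e), weight = 1)
  }))
  list(t1 = m1, t2 = m2)
}

# minimal rotated/unrotated FA-fit object for FAST unit tests
fa_stub <- function(loadings, scores, env_intercepts = NULL, rotated = FALSE) {
  structure(list(loadings = as.matrix(loadings),
                 scores = as.matrix(scores),
                 specific_vars = rep(0, nrow(as.matrix(loadings))),
                 env_intercepts = env_intercepts,
                 n_factors = ncol(as.matrix(loadings)),
                 year_sites = paste0("S", seq_len(nrow(as.matrix(loadings)))),
                 genotypes = rownames(as.matrix(scores)),
                 converged = TRUE, rotated = rotated),
            class = "fa_fit")
}

# metadata mirroring the study layout: 45 genotypes, 5 year-sites,
# 36 genotypes per year-site, one cell removed
study_meta <- function() {
  geno <- sprintf("G%02d", 1:45)
  pres <- list(D19 = geno[1:36], F19 = geno[1:36], S19 = geno[1:36],
               D20 = geno[10:45], F20 = geno[10:45])
  meta <- do.call(rbind, lapply(names(pres), function(s) {
    data.frame(genotype = pres[[s]], year_site = s,
               stringsAsFactors = FALSE)
  }))
  meta[-1, ] # one outlier cell removed
}

# cell-level feature table with genotype and environment latents
cell_features <- function(seed, m = 40, p = 5, env_effect = function(v) v,
                          v = NULL, beta_env = 1.5, noise = 0.3) {
  set.seed(seed)
  u <- rnorm(m)
  if (is.null(v)) v <- rnorm(p, 0, 1.2)
  X <- do.call(rbind, lapply(seq_len(p), function(j) {
    sapply(1:6, function(k) 0.7 * u + 0.8 * v[j] + rnorm(m, 0, 0.4))
  }))
  colnames(X) <- paste0("f", 1:6)
  df <- data.frame(genotype = rep(sprintf("g%02d", seq_len(m)), p),
                   year_site = rep(paste0("E", seq_len(p)), each = m), X)
  df$response <- rep(u, p) + beta_env * rep(env_effect(v), each = m) +
    rnorm(m * p, 0, noise)
  df
}
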