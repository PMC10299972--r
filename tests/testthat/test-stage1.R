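test_that("on a flat field BLUEs collapse to raw genotype means", {
  cfg <- sim_config(n_genotypes = 30, sigma2_spatial = 0, sigma2_row = 0,
                    sigma2_col = 0, sigma2_e = 1e-6, se_lognormal_sd = 0,
                    missing_pattern = 0, seed = 3)
  pl <- subset(simulate_met(cfg)$plots,
               trait == "yield" & year_site == "Delley_2019")
  bl <- stage1_blues(fit_stage1(pl, "BLUE"))
  raw <- tapply(pl$value, pl$genotype, mean)
  expect_lt(max(abs(bl$blue - raw[bl$genotype])), 1e-3)
  # emitted weights are exactly 1/se^2
  expect_equal(bl$weight, 1 / bl$se^2)
})

test_that("duplicate plot positions and bad SEs are rejected", {
  cfg <- sim_config(n_genotypes = 20, seed = 1)
  pl <- subset(simulate_met(cfg)$plots,
               trait == "yield" & year_site == "FIP_2019")
  pl2 <- rbind(pl, pl[1, ])
  expect_error(fit_stage1(pl2, "BLUE"), "duplicate")
  pl3 <- pl
  pl3$se[1] <- 0
  expect_error(fit_stage1(pl3, "BLUE"), "positive")
})

test_that("repeatability mode requires replication", {
  cfg <- sim_config(n_genotypes = 20, seed = 1)
  pl <- subset(simulate_met(cfg)$plots,
               trait == "yield" & year_site == "FIP_2019" & replicate == 1)
  expect_error(fit_stage1(pl, "repeatability"), "replicated")
})

test_that("adding a constant shifts every BLUE by exactly that constant", {
  cfg <- sim_config(n_genotypes = 25, seed = 6)
  pl <- subset(simulate_met(cfg)$plots,
               trait == "yield" & year_site == "Strickhof_2019")
  b1 <- stage1_blues(fit_stage1(pl, "BLUE"))
  pl$value <- pl$value + 5
  b2 <- stage1_blues(fit_stage1(pl, "BLUE"))
  expect_equal(b2$blue, b1$blue + 5, tolerance = 1e-3)
})

test_that("spatial adjustment beats raw means under a field trend", {
  mse <- sapply(1:5, function(s) {
    cfg <- sim_config(n_genotypes = 30, sigma2_spatial = 0.5,
                      sigma2_row = 0.05, sigma2_col = 0.05,
                      sigma2_e = 0.15, missing_pattern = 0, seed = s)
    sim <- simulate_met(cfg)
    pl <- subset(sim$plots, trait == "yield" & year_site == "FIP_2019")
    tru <- sim$truth$cell_values[, "FIP_2019"]
    bl <- stage1_blues(fit_stage1(pl, "BLUE"))
    raw <- tapply(pl$value, pl$genotype, mean)
    ctr <- function(v) v - mean(v)
    c(blue = mean((ctr(bl$blue) - ctr(tru[bl$genotype]))^2),
      raw = mean((ctr(raw[bl$genotype]) - ctr(tru[bl$genotype]))^2))
  })
  expect_true(all(mse["blue", ] < mse["raw", ]))
})

test_that("fitted surface is centered and uncorrelated with BLUEs on null trends", {
  cfg <- sim_config(n_genotypes = 30, sigma2_spatial = 0, sigma2_row = 0,
                    sigma2_col = 0, missing_pattern = 0, seed = 9)
  pl <- subset(simulate_met(cfg)$plots,
               trait == "yield" & year_site == "FIP_2019")
  f <- fit_stage1(pl, "BLUE")
  expect_equal(mean(f$surface), 0, tolerance = 1e-10)
  bl <- stage1_blues(f)
  expect_lt(abs(cor(f$surface, bl$blue[match(pl$genotype, bl$genotype)])), 0.1)
})

test_that("SEs shrink with replication", {
  cfg <- sim_config(n_genotypes = 25, missing_pattern = 0, seed = 4)
  pl <- subset(simulate_met(cfg)$plots,
               trait == "yield" & year_site == "Delley_2019")
  # keep one genotype at a single surviving plot
  g1 <- pl$genotype[1]
  pl_cut <- pl[!(pl$genotype == g1 & pl$replicate > 1), ]
  bl <- stage1_blues(fit_stage1(pl_cut, "BLUE"))
  expect_gt(bl$se[bl$genotype == g1], max(bl$se[bl$genotype != g1]))
})

test_that("Oakey repeatability matches the mixed-model-equation oracle", {
  # toy 3 genotypes x 2 reps, unit weights: sigma2_g = 15, sigma2_e = 2,
  # closed form h2 = s2g / (s2g + s2e/r) = 0.9375
  toy <- data.frame(year_site = "S", genotype = rep(1:3, each = 2),
                    row = 1:6, col = 1, x = 1:6, y = 1,
                    replicate = rep(1:2, 3), trait = "t",
                    value = c(10, 12, 14, 16, 18, 20), se = 1)
  ft <- fit_stage1(toy, "repeatability", spatial = FALSE)
  expect_equal(repeatability_oakey(ft), 0.9375, tolerance = 1e-3)
  # mean-PEV variant keeps the mean-confounded direction
  expect_equal(repeatability_oakey(ft, "mean_pev"), 0.625, tolerance = 1e-3)
})

test_that("repeatability matches the plot-basis formula on balanced designs", {
  for (s in 1:3) {
    cfg <- sim_config(n_genotypes = 40, sigma2_g = 0.5,
                      loadings_true = matrix(0, 5, 2), psi_true = rep(0, 5),
                      sigma2_spatial = 0, sigma2_row = 0, sigma2_col = 0,
                      sigma2_e = 0.2, se_lognormal_sd = 0,
                      missing_pattern = 0, seed = s)
    pl <- subset(simulate_met(cfg)$plots,
                 trait == "yield" & year_site == "Delley_2019")
    ft <- fit_stage1(pl, "repeatability", spatial = FALSE)
    s2g <- ft$fit$vp$genotype$sigma2
    s2e_obs <- ft$sigma2_e * mean(pl$se^2) # residual on the observation scale
    expect_equal(repeatability_oakey(ft), s2g / (s2g + s2e_obs / 4),
                 tolerance = 0.02)
  }
})

test_that("repeatability vanishes without genetic variance", {
  h2 <- sapply(1:5, function(s) {
    cfg <- sim_config(n_genotypes = 30, sigma2_g = 0,
                      loadings_true = matrix(0, 5, 2), psi_true = rep(0, 5),
                      missing_pattern = 0, seed = 200 + s)
    pl <- subset(simulate_met(cfg)$plots,
                 trait == "yield" & year_site == "FIP_2019")
    repeatability_oakey(fit_stage1(pl, "repeatability"))
  })
  expect_lt(mean(h2), 0.05)
})

test_that("BLUEs track the simulated truth when heritable", {
  cfg <- sim_config(n_genotypes = 40, sigma2_g = 0.6, sigma2_e = 0.2,
                    missing_pattern = 0, seed = 10)
  sim <- simulate_met(cfg)
  pl <- subset(sim$plots, trait == "yield" & year_site == "FIP_2019")
  bl <- stage1_blues(fit_stage1(pl, "BLUE"))
  expect_gte(cor(bl$blue, sim$truth$cell_values[bl$genotype, "FIP_2019"]), 0.9)
})
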