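# Synthetic multi-environment-trial generator with known ground truth.
#
# Emulates the structure of a winter-wheat variety-testing MET: genotype
# main effects, factor-analytic GxE covariance across year-sites, a
# smooth spatial field trend plus random row/column effects within each
# year-site, heteroscedastic plot errors with reported standard errors,
# correlated secondary (HTFP) traits linked to the target trait, a
# negatively linked grain-protein trait measured at genotype level, and
# ordinal breeder decisions driven by true performance and stability.

#' Configuration for the synthetic MET generator
#'
#' Defaults emulate a 45-genotype, 5 year-site variety-testing trial with
#' four replicates (three in one year-site), roughly 20% of genotypes
#' absent per year-site, a two-factor GxE covariance for the target trait
#' (yield, t/ha), and eleven linked intermediate HTFP traits.
#'
#' @param n_genotypes Number of genotypes.
#' @param year_sites Named list; per year-site a list with `n_rows`,
#'   `n_cols`, `n_reps`.
#' @param sigma2_g Genotype main-effect variance of the target trait.
#' @param loadings_true p x k matrix of true environment loadings.
#' @param psi_true Length-p non-negative specific (lack-of-fit) variances.
#' @param env_intercepts Length-p year-site means of the target trait.
#' @param sigma2_spatial,sigma2_row,sigma2_col Field-trend and row/column
#'   variances.
#' @param sigma2_e Plot residual variance of the target trait.
#' @param se_lognormal_sd Spread of the per-plot lognormal factor applied
#'   to `sqrt(sigma2_e)` to produce heterogeneous reported SEs (0 gives
#'   homoscedastic plots with `se = sqrt(sigma2_e)`).
#' @param trait_links Named list of secondary traits; each entry a list
#'   with `coef` (regression on the genotype main effect), `sigma2_ind`
#'   (independent genetic variance), `sigma2_site` (year-site shift
#'   variance), `sigma2_e` (plot error variance), `mean`.
#' @param protein_link Negative coefficient linking grain-protein genetic
#'   values to yield genetic values (percent per t/ha).
#' @param protein_mean,protein_sigma2_ind,protein_sigma2_e Grain-protein
#'   mean, independent genetic variance and measurement error variance.
#' @param missing_pattern Fraction of genotypes absent per year-site
#'   (whole genotype x year-site cells dropped).
#' @param decision List controlling breeder decisions: `w_op`, `w_rmsd`
#'   (weights of true OP and RMSD in the latent index), `noise_sd`, and
#'   four descending `thresholds` on the standardized latent scale.
#' @param seed Integer seed; identical configurations give identical output.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_genotypes = 45,
                       year_sites = default_year_sites(n_genotypes,
                                                       missing_pattern),
                       sigma2_g = 0.35,
                       loadings_true = default_loadings(length(year_sites)),
                       psi_true = rep(0.05, length(year_sites)),
                       env_intercepts = default_env_intercepts(names(year_sites)),
                       sigma2_spatial = 0.2,
                       sigma2_row = 0.02,
                       sigma2_col = 0.02,
                       sigma2_e = 0.15,
                       se_lognormal_sd = 0.25,
                       trait_links = default_trait_links(),
                       protein_link = -0.8,
                       protein_mean = 13,
                       protein_sigma2_ind = 0.3,
                       protein_sigma2_e = 0.05,
                       missing_pattern = 0.2,
                       decision = list(w_op = 1, w_rmsd = 0.5, noise_sd = 0.5,
                                       thresholds = c(1.5, 1.0, 0.5, 0)),
                       seed = 1L) {
  p <- length(year_sites)
  loadings_true <- as.matrix(loadings_true)
  if (p < 2) stop("need at least 2 year-sites")
  if (nrow(loadings_true) != p) stop("loadings_true must have one row per year-site")
  if (ncol(loadings_true) > 2) stop("at most 2 factors supported")
  stopifnot(length(psi_true) == p, all(psi_true >= 0),
            length(env_intercepts) == p,
            sigma2_g >= 0, sigma2_spatial >= 0, sigma2_row >= 0,
            sigma2_col >= 0, sigma2_e >= 0,
            missing_pattern >= 0, missing_pattern < 1)
  n_present <- n_genotypes - floor(missing_pattern * n_genotypes)
  for (ys in names(year_sites)) {
    g <- year_sites[[ys]]
    if (g$n_rows * g$n_cols < n_present * g$n_reps) {
      stop("grid for ", ys, " too small: ", g$n_rows, "x", g$n_cols,
           " cannot hold ", n_present, " genotypes x ", g$n_reps, " reps")
    }
  }
  cfg <- list(n_genotypes = as.integer(n_genotypes), year_sites = year_sites,
              sigma2_g = sigma2_g, loadings_true = loadings_true,
              psi_true = psi_true, env_intercepts = env_intercepts,
              sigma2_spatial = sigma2_spatial, sigma2_row = sigma2_row,
              sigma2_col = sigma2_col, sigma2_e = sigma2_e,
              se_lognormal_sd = se_lognormal_sd, trait_links = trait_links,
              protein_link = protein_link, protein_mean = protein_mean,
              protein_sigma2_ind = protein_sigma2_ind,
              protein_sigma2_e = protein_sigma2_e,
              missing_pattern = missing_pattern, decision = decision,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Default year-site layouts for the synthetic MET
#'
#' Five year-sites over two years and three sites, four replicates
#' except one year-site with three; grids sized to hold the genotypes
#' present after the missing-cell pattern.
#'
#' @param n_genotypes Number of genotypes in the trial.
#' @param missing_pattern Fraction of genotypes absent per year-site.
#' @return Named list of per-year-site grids (`n_rows`, `n_cols`,
#'   `n_reps`).
#' @export
default_year_sites <- function(n_genotypes = 45, missing_pattern = 0.2) {
  n_present <- n_genotypes - floor(missing_pattern * n_genotypes)
  dim4 <- ceiling(sqrt(n_present * 4))
  dim3 <- ceiling(sqrt(n_present * 3))
  list(
    Delley_2019    = list(n_rows = dim4, n_cols = dim4, n_reps = 4),
    Delley_2020    = list(n_rows = dim4, n_cols = dim4, n_reps = 4),
    FIP_2019       = list(n_rows = dim4, n_cols = dim4, n_reps = 4),
    FIP_2020       = list(n_rows = dim3, n_cols = dim3, n_reps = 3),
    Strickhof_2019 = list(n_rows = dim4, n_cols = dim4, n_reps = 4))
}

default_loadings <- function(p) {
  # first factor: common positive response; second: mild contrasts
  l1 <- seq(0.4, 0.6, length.out = p)
  l2 <- 0.2 * (-1)^seq_len(p) * seq(1, 0.3, length.out = p)
  l2[1] <- 0 # identification-friendly truth; rotation handles the rest
  cbind(l1, l2)
}

default_env_intercepts <- function(nm) {
  v <- c(6.3, 4.9, 7.5, 6.1, 6.6)[seq_along(nm)]
  if (length(v) < length(nm)) v <- c(v, rep(6, length(nm) - length(v)))
  stats::setNames(v, nm)
}

default_trait_links <- function() {
  list( # C: dose-response curve parameters; T: timing; Q: quantities
    r_max      = list(coef =  0.6, sigma2_ind = 0.5, sigma2_site = 0.3, sigma2_e = 0.6,  mean = 10),
    T_min      = list(coef =  0.5, sigma2_ind = 0.6, sigma2_site = 0.3, sigma2_e = 0.8,  mean = 2),
    lrc        = list(coef =  0.4, sigma2_ind = 0.6, sigma2_site = 0.2, sigma2_e = 0.8,  mean = -5),
    t_PH_start = list(coef =  0.5, sigma2_ind = 0.5, sigma2_site = 0.5, sigma2_e = 0.7,  mean = 650),
    t_PH_stop  = list(coef = -0.3, sigma2_ind = 0.6, sigma2_site = 0.5, sigma2_e = 0.7,  mean = 1400),
    t_dLA_max  = list(coef = -0.4, sigma2_ind = 0.6, sigma2_site = 0.4, sigma2_e = 0.8,  mean = 800),
    t_LA_max   = list(coef = -0.2, sigma2_ind = 0.7, sigma2_site = 0.4, sigma2_e = 0.8,  mean = 1100),
    PH_max     = list(coef =  0.3, sigma2_ind = 0.6, sigma2_site = 0.3, sigma2_e = 0.4,  mean = 95),
    LA_tPH15   = list(coef =  0.4, sigma2_ind = 0.7, sigma2_site = 0.4, sigma2_e = 0.9,  mean = 1.8),
    LA_max     = list(coef =  0.3, sigma2_ind = 0.8, sigma2_site = 0.4, sigma2_e = 0.9,  mean = 4.5),
    n_tiller   = list(coef =  0.7, sigma2_ind = 0.5, sigma2_site = 0.4, sigma2_e = 0.6,  mean = 550))
}

#' Categories of the default intermediate HTFP traits
#'
#' @return Named character vector mapping trait name to category
#'   ("C" dose-response, "T" timing, "Q" quantity).
#' @export
trait_categories <- function() {
  c(r_max = "C", T_min = "C", lrc = "C",
    t_PH_start = "T", t_PH_stop = "T", t_dLA_max = "T", t_LA_max = "T",
    PH_max = "Q", LA_tPH15 = "Q", LA_max = "Q", n_tiller = "Q")
}

# smooth bivariate field trend: random combination of low-order sinusoid
# products, rescaled to the requested variance over the plots
sim_surface <- function(x, y, nx, ny, sigma2) {
  if (sigma2 <= 0) return(rep(0, length(x)))
  u <- (x - 0.5) / nx; v <- (y - 0.5) / ny
  bx <- cbind(sin(pi * u), cos(pi * u), sin(2 * pi * u))
  by <- cbind(sin(pi * v), cos(pi * v), sin(2 * pi * v))
  s <- rep(0, length(x))
  cf <- stats::rnorm(9)
  idx <- 1
  for (a in 1:3) for (b in 1:3) {
    s <- s + cf[idx] * bx[, a] * by[, b]
    idx <- idx + 1
  }
  sdv <- stats::sd(s)
  if (sdv < 1e-12) return(rep(0, length(x)))
  s / sdv * sqrt(sigma2)
}

sim_truth <- function(cfg) {
  m <- cfg$n_genotypes
  p <- length(cfg$year_sites)
  k <- ncol(cfg$loadings_true)
  geno <- sprintf("G%03d", seq_len(m))
  sites <- names(cfg$year_sites)
  g <- stats::rnorm(m, 0, sqrt(cfg$sigma2_g))
  f <- matrix(stats::rnorm(m * k), m, k)
  delta <- matrix(stats::rnorm(m * p, 0, rep(sqrt(cfg$psi_true), each = m)), m, p)
  gxe <- f %*% t(cfg$loadings_true) + delta
  cell <- outer(g, rep(1, p)) + sweep(gxe, 2, cfg$env_intercepts, "+")
  dimnames(cell) <- list(geno, sites)
  names(g) <- geno
  rownames(f) <- geno
  # true OP/RMSD from the rotated true loadings (plus genotype main effect)
  sv <- svd(cfg$loadings_true)
  Lr <- sv$u %*% diag(sv$d, k, k)
  Fr <- f %*% sv$v
  for (h in seq_len(k)) if (sum(Lr[, h]) < 0) {
    Lr[, h] <- -Lr[, h]; Fr[, h] <- -Fr[, h]
  }
  op_true <- g + mean(Lr[, 1]) * Fr[, 1]
  rmsd_true <- if (k > 1) {
    sqrt(rowMeans((Fr[, -1, drop = FALSE] %*% t(Lr[, -1, drop = FALSE]))^2))
  } else rep(0, m)
  dlat <- cfg$decision$w_op * op_true - cfg$decision$w_rmsd * rmsd_true
  dlat <- as.vector(scale(dlat)) + stats::rnorm(m, 0, cfg$decision$noise_sd)
  names(dlat) <- names(rmsd_true) <- geno
  # secondary trait genetic values
  sec <- lapply(cfg$trait_links, function(lk) {
    lk$mean + lk$coef * g + stats::rnorm(m, 0, sqrt(lk$sigma2_ind))
  })
  protein <- cfg$protein_mean + cfg$protein_link * g +
    stats::rnorm(m, 0, sqrt(cfg$protein_sigma2_ind))
  names(protein) <- geno
  # which genotypes appear in which year-site
  n_miss <- floor(cfg$missing_pattern * m)
  present <- lapply(sites, function(s) {
    if (n_miss == 0) geno else setdiff(geno, sample(geno, n_miss))
  })
  names(present) <- sites
  list(genotype_values = g, scores_true = f, env_effects = cfg$env_intercepts,
       cell_values = cell, loadings_true = cfg$loadings_true,
       psi_true = cfg$psi_true, op_true = op_true, rmsd_true = rmsd_true,
       decision_latent = dlat, secondary_values = sec,
       protein_values = protein, present = present, genotypes = geno)
}

#' Simulate plot-level MET data with known ground truth
#'
#' Generates, per year-site, a randomized field layout and plot values
#' `value = year-site intercept + genotype cell value + spatial surface +
#' row effect + column effect + N(0, se^2)` for the target trait
#' (`yield`) and all configured secondary traits, with reported standard
#' errors `se = sqrt(sigma2_e) * lognormal factor` so that weights
#' `w = 1/se^2` are genuinely heterogeneous. Grain protein is generated
#' at the genotype x year-site level (merged probes, unit weights).
#'
#' @param config A [sim_config()].
#' @return List with `plots` (data.frame: year_site, genotype, row, col,
#'   x, y, replicate, trait, value, se), `genotype_means` (grain protein
#'   as adjusted means with unit weights), `truth` (true effects used for
#'   parameter-recovery checks), and `config`.
#' @export
simulate_met <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  truth <- sim_truth(config)
  sites <- names(config$year_sites)
  out <- vector("list", length(sites))
  tau <- config$se_lognormal_sd
  for (si in seq_along(sites)) {
    s <- sites[si]
    grid <- config$year_sites[[s]]
    pres <- truth$present[[s]]
    n_plot <- length(pres) * grid$n_reps
    pos <- sample(grid$n_rows * grid$n_cols, n_plot)
    row <- (pos - 1L) %/% grid$n_cols + 1L
    col <- (pos - 1L) %% grid$n_cols + 1L
    genotype <- rep(pres, each = grid$n_reps)
    replicate <- rep(seq_len(grid$n_reps), times = length(pres))
    re <- stats::rnorm(grid$n_rows, 0, sqrt(config$sigma2_row))
    ce <- stats::rnorm(grid$n_cols, 0, sqrt(config$sigma2_col))
    surf <- sim_surface(col, row, grid$n_cols, grid$n_rows, config$sigma2_spatial)
    base <- truth$cell_values[genotype, s] + surf + re[row] + ce[col]
    tabs <- vector("list", 1 + length(config$trait_links))
    se <- sqrt(config$sigma2_e) * exp(stats::rnorm(n_plot, 0, tau))
    tabs[[1]] <- data.frame(
      year_site = s, genotype = genotype, row = row, col = col,
      x = col, y = row, replicate = replicate, trait = "yield",
      value = base + stats::rnorm(n_plot, 0, se), se = se,
      stringsAsFactors = FALSE)
    for (ti in seq_along(config$trait_links)) {
      tr <- names(config$trait_links)[ti]
      lk <- config$trait_links[[tr]]
      shift <- stats::rnorm(1, 0, sqrt(lk$sigma2_site))
      se_t <- sqrt(lk$sigma2_e) * exp(stats::rnorm(n_plot, 0, tau))
      tabs[[1 + ti]] <- data.frame(
        year_site = s, genotype = genotype, row = row, col = col,
        x = col, y = row, replicate = replicate, trait = tr,
        value = truth$secondary_values[[tr]][match(genotype, truth$genotypes)] +
          shift + surf + re[row] + ce[col] + stats::rnorm(n_plot, 0, se_t),
        se = se_t, stringsAsFactors = FALSE)
    }
    out[[si]] <- do.call(rbind, tabs)
  }
  plots <- do.call(rbind, out)
  rownames(plots) <- NULL
  prot <- do.call(rbind, lapply(sites, function(s) {
    pres <- truth$present[[s]]
    data.frame(year_site = s, genotype = pres, trait = "protein",
               blue = truth$protein_values[pres] +
                 stats::rnorm(length(pres), 0, sqrt(config$protein_sigma2_e)),
               se = 1, weight = 1, stringsAsFactors = FALSE)
  }))
  rownames(prot) <- NULL
  list(plots = plots, genotype_means = prot, truth = truth, config = config)
}

#' Simulate stage-2 adjusted means directly
#'
#' Bypasses the field layer: genotype x year-site BLUEs are drawn as
#' `true cell value + N(0, se^2)` with heterogeneous reported SEs, giving
#' the `AdjustedMeans` input of the across-year-site stage without the
#' cost of per-plot simulation. Used for estimator-recovery studies.
#'
#' @param config A [sim_config()].
#' @param se_mean Mean reported SE of a year-site BLUE (default
#'   `sqrt(sigma2_e)/2`).
#' @return List with `means` (year_site, genotype, trait, blue, se,
#'   weight) and `truth`.
#' @export
simulate_adjusted_means <- function(config, se_mean = sqrt(config$sigma2_e) / 2) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  truth <- sim_truth(config)
  sites <- names(config$year_sites)
  tau <- config$se_lognormal_sd
  means <- do.call(rbind, lapply(sites, function(s) {
    pres <- truth$present[[s]]
    se <- se_mean * exp(stats::rnorm(length(pres), 0, tau))
    data.frame(year_site = s, genotype = pres, trait = "yield",
               blue = truth$cell_values[pres, s] + stats::rnorm(length(pres), 0, se),
               se = se, weight = 1 / se^2, stringsAsFactors = FALSE)
  }))
  rownames(means) <- NULL
  list(means = means, truth = truth)
}

#' Simulate breeder selection decisions
#'
#' Thresholds the latent decision index (weighted true overall
#' performance minus weighted true stability RMSD, plus noise, carried in
#' the truth object) into the five-level selection scale used in
#' early-generation wheat breeding.
#'
#' @param truth Truth list from [simulate_met()] (or its `$truth`).
#' @param config The matching [sim_config()].
#' @return Named character vector: genotype -> one of `"selected"`,
#'   `"sister_selected"`, `"repeated"`, `"sister_repeated"`,
#'   `"discarded"`.
#' @export
simulate_decisions <- function(truth, config) {
  if (!is.null(truth$truth)) truth <- truth$truth
  lat <- truth$decision_latent
  th <- config$decision$thresholds
  stopifnot(length(th) == 4, !is.unsorted(rev(th)))
  lab <- c("selected", "sister_selected", "repeated", "sister_repeated",
           "discarded")
  out <- lab[5 - findInterval(lat, rev(th))]
  stats::setNames(out, names(lat))
}

#' Cumulative growing degree days
#'
#' Averages hourly temperatures per calendar day, subtracts the base
#' temperature, clamps negative values at zero, and accumulates.
#'
#' @param timestamp POSIXct (or coercible) hourly timestamps, no
#'   duplicates.
#' @param temp Temperatures in degrees Celsius.
#' @param t_base Base temperature (default 0).
#' @return data.frame with `date`, daily `gdd`, and cumulative `gdd_cum`
#'   (degree-Celsius days).
#' @export
gdd <- function(timestamp, temp, t_base = 0) {
  if (length(timestamp) == 0) stop("empty temperature series")
  if (anyDuplicated(timestamp)) stop("duplicate timestamps")
  stopifnot(length(timestamp) == length(temp))
  day <- as.Date(timestamp)
  daily <- tapply(temp, day, mean)
  g <- pmax(daily - t_base, 0)
  data.frame(date = as.Date(names(daily)), gdd = as.numeric(g),
             gdd_cum = cumsum(as.numeric(g)), row.names = NULL)
}
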