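# Stage 1: per-year-site spatial analysis.
#
# One weighted mixed model per (year-site, trait): genotype effects
# (fixed for BLUEs, random for repeatability), a smooth bivariate spatial
# surface in mixed-model P-spline form, random row and column effects,
# and plot residuals var(e) = sigma2 / w with w = 1/SE^2 from the
# upstream dynamic-modeling step.

# Cubic B-spline basis over u with nseg segments (equidistant knots).
bspline_basis <- function(u, nseg) {
  xl <- min(u); xr <- max(u)
  if (xr <= xl) xr <- xl + 1
  dx <- (xr - xl) / nseg
  knots <- seq(xl - 3 * dx, xr + 3 * dx, by = dx)
  splines::splineDesign(knots, u, ord = 4, outer.ok = TRUE)
}

second_diff_penalty <- function(K) {
  D <- diff(diag(K), differences = 2)
  crossprod(D)
}

# Tensor-product P-spline surface in mixed-model form: returns the
# bilinear fixed part (x, y, xy) and the random basis Z (iid coefficients)
# obtained from the eigen-decomposition of the combined difference penalty.
spatial_mm_basis <- function(x, y, nseg_x, nseg_y) {
  Bx <- bspline_basis(x, nseg_x)
  By <- bspline_basis(y, nseg_y)
  Kx <- ncol(Bx); Ky <- ncol(By)
  B <- matrix(0, length(x), Kx * Ky)
  for (a in seq_len(Kx)) {
    B[, (a - 1) * Ky + seq_len(Ky)] <- Bx[, a] * By
  }
  S <- kronecker(second_diff_penalty(Kx), diag(Ky)) +
    kronecker(diag(Kx), second_diff_penalty(Ky))
  es <- eigen(S, symmetric = TRUE)
  pos <- es$values > max(es$values) * 1e-10
  Z <- B %*% es$vectors[, pos] %*% diag(1 / sqrt(es$values[pos]))
  xs <- scale(x); ys <- scale(y)
  Xpoly <- cbind(sp_x = as.vector(xs), sp_y = as.vector(ys),
                 sp_xy = as.vector(xs * ys))
  list(X = Xpoly, Z = Z)
}

#' Fit the stage-1 spatial model for one year-site and trait
#'
#' Weighted mixed model for plot values of a single year-site and trait:
#' genotype term (fixed in `"BLUE"` mode, random in `"repeatability"`
#' mode), tensor-product P-spline surface (bilinear fixed part plus
#' penalized smooth as an iid random basis), random row and column
#' effects, residual `var(e) = sigma2 / w` with `w = 1/se^2`.
#'
#' @param plots data.frame with columns `year_site`, `genotype`, `row`,
#'   `col`, `x`, `y`, `replicate`, `trait`, `value`, `se` for a single
#'   year-site and trait.
#' @param mode `"BLUE"` (genotype fixed, for adjusted means) or
#'   `"repeatability"` (genotype random, for Oakey repeatability).
#' @param spatial Fit the smooth surface (default TRUE; FALSE drops both
#'   the bilinear part and the penalized smooth).
#' @param nseg_cap Maximum number of spline segments per direction
#'   (default 20; about one knot per two rows/columns otherwise).
#' @return Object of class `"stage1_fit"`: the underlying `reml_fit`,
#'   genotype effects, the centered fitted surface at plot coordinates,
#'   row/column BLUPs, and `sigma2_e`.
#' @export
fit_stage1 <- function(plots, mode = c("BLUE", "repeatability"),
                       spatial = TRUE, nseg_cap = 20) {
  mode <- match.arg(mode)
  req <- c("year_site", "genotype", "row", "col", "x", "y", "value", "se")
  if (!all(req %in% names(plots))) {
    stop("plots must contain columns: ", paste(req, collapse = ", "))
  }
  if (length(unique(plots$year_site)) != 1) stop("fit_stage1 expects a single year-site")
  if ("trait" %in% names(plots) && length(unique(plots$trait)) != 1) {
    stop("fit_stage1 expects a single trait")
  }
  if (anyDuplicated(plots[, c("row", "col")])) {
    stop("duplicate (row, col) plot records")
  }
  if (any(plots$se <= 0)) stop("reported SEs must be positive")
  geno <- factor(plots$genotype)
  reps <- table(geno)
  if (mode == "repeatability" && max(reps) < 2) {
    stop("repeatability mode needs replicated genotypes (variance not separable)")
  }
  w <- 1 / plots$se^2
  n <- nrow(plots)

  terms <- list()
  if (spatial) {
    sp <- spatial_mm_basis(plots$x, plots$y,
                           nseg_x = min(max(4, ceiling(length(unique(plots$x)) / 2)), nseg_cap),
                           nseg_y = min(max(4, ceiling(length(unique(plots$y)) / 2)), nseg_cap))
    terms$spatial <- ranef("spatial", vs_id(), Z = sp$Z)
  }
  if (length(unique(plots$row)) > 1) {
    terms$row <- ranef("row", vs_id(), inner = factor(plots$row))
  }
  if (length(unique(plots$col)) > 1) {
    terms$col <- ranef("col", vs_id(), inner = factor(plots$col))
  }

  if (mode == "BLUE") {
    X <- stats::model.matrix(~ geno - 1)
    colnames(X) <- levels(geno)
  } else {
    X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
    terms$genotype <- ranef("genotype", vs_id(), inner = geno)
  }
  if (spatial) X <- cbind(X, sp$X)

  fit <- reml_fit(plots$value, X, terms, weights = w)

  surface <- rep(0, n)
  if (spatial) {
    surface <- as.vector(sp$Z %*% fit$blup$spatial) +
      as.vector(sp$X %*% fit$beta[c("sp_x", "sp_y", "sp_xy")])
    surface <- surface - mean(surface)
  }
  geno_eff <- if (mode == "BLUE") fit$beta[levels(geno)] else fit$blup$genotype
  out <- list(year_site = as.character(plots$year_site[1]),
              trait = if ("trait" %in% names(plots)) as.character(plots$trait[1]) else NA_character_,
              mode = mode, fit = fit, genotype_effects = geno_eff,
              genotypes = levels(geno), surface = surface,
              row_effects = if (!is.null(terms$row)) fit$blup$row else NULL,
              col_effects = if (!is.null(terms$col)) fit$blup$col else NULL,
              sigma2_e = fit$vp$residual$sigma2, converged = fit$converged)
  class(out) <- "stage1_fit"
  out
}

#' Extract genotype BLUEs with weights from a stage-1 fit
#'
#' Per-genotype adjusted means, standard errors from the diagonal of the
#' fixed-effect variance-covariance matrix, and stage-2 weights
#' `w = 1/se^2`.
#'
#' @param fit A `"stage1_fit"` in `"BLUE"` mode.
#' @return data.frame: `year_site`, `genotype`, `trait`, `blue`, `se`,
#'   `weight` (the `AdjustedMeans` table of the two-stage analysis).
#' @export
stage1_blues <- function(fit) {
  stopifnot(inherits(fit, "stage1_fit"))
  if (fit$mode != "BLUE") stop("stage1_blues needs a fit with mode = 'BLUE'")
  g <- fit$genotypes
  se <- sqrt(diag(fit$fit$vcov_beta)[g])
  data.frame(year_site = fit$year_site, genotype = g, trait = fit$trait,
             blue = as.numeric(fit$genotype_effects[g]), se = as.numeric(se),
             weight = 1 / as.numeric(se)^2, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Within-year-site repeatability (generalized heritability, Oakey form)
#'
#' Generalized heritability from the genotype prediction-error-variance
#' matrix of a genotype-random stage-1 fit. The default `"eigen"` method
#' averages `1 - lambda_i` over the m-1 smallest eigenvalues of
#' `PEV / sigma2_g`, dropping the dimension confounded with the trial
#' mean; `"mean_pev"` uses `1 - tr(PEV) / (m sigma2_g)`.
#'
#' @param fit A `"stage1_fit"` in `"repeatability"` mode (or any
#'   `reml_fit` with a random term named `"genotype"`).
#' @param method `"eigen"` (default) or `"mean_pev"`.
#' @return Repeatability in \[0, 1\].
#' @export
repeatability_oakey <- function(fit, method = c("eigen", "mean_pev")) {
  method <- match.arg(method)
  if (inherits(fit, "stage1_fit")) {
    if (fit$mode != "repeatability") {
      stop("repeatability needs a fit with mode = 'repeatability'")
    }
    fit <- fit$fit
  }
  stopifnot(inherits(fit, "reml_fit"))
  s2g <- fit$vp$genotype$sigma2
  if (is.null(s2g)) stop("fit has no random 'genotype' term")
  if (s2g < 1e-7) return(0)
  P <- fit$pev("genotype")
  m <- nrow(P)
  h2 <- if (method == "eigen") {
    lam <- sort(eigen(P / s2g, symmetric = TRUE, only.values = TRUE)$values)
    mean(1 - lam[seq_len(m - 1)])
  } else {
    1 - sum(diag(P)) / (m * s2g)
  }
  min(max(h2, 0), 1)
}
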