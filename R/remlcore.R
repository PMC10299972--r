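# Generic Gaussian REML engine on sparse mixed-model equations.
#
# Model: y = X beta + sum_r Z_r u_r + e,  var(u_r) structured per term,
# var(e) = sigma2 * W^-1 (weighted diagonal) or an unstructured 2x2
# block per group (bivariate models where interaction and residual are
# confounded). Variance parameters are optimized on unconstrained scales
# (log for variances, log-Cholesky for 2x2 blocks, raw for factor
# loadings); the restricted likelihood is evaluated through the sparse
# Cholesky factor of the mixed-model coefficient matrix.

#' Variance structure specifications
#'
#' Constructors for the covariance structures a random term (or the
#' residual) of [reml_fit()] can take:
#' \describe{
#'   \item{`vs_id()`}{a single variance, `sigma2 * I`.}
#'   \item{`vs_diag(dim)`}{heterogeneous variances, one per level of the
#'     outer factor (e.g. per year-site interaction variances, `Diag`).}
#'   \item{`vs_us2()`}{unstructured symmetric 2x2 covariance (log-Cholesky
#'     parameterized), for bivariate genotype or residual terms.}
#'   \item{`vs_rr_diag(dim, n_factors)`}{reduced-rank (factor-analytic)
#'     plus diagonal structure `Lambda Lambda' + diag(Psi)` across `dim`
#'     environments with `n_factors` factors; the factor part is fitted
#'     through latent genotype scores so the implied covariance is always
#'     positive semidefinite. Identification: upper triangle of `Lambda`
#'     fixed to zero.}
#' }
#'
#' @param dim Number of levels of the structured dimension (environments
#'   for `Diag`/factor-analytic structures).
#' @param n_factors Number of factors (1 or 2) for the reduced-rank part.
#' @return An object of class `"vspec"`.
#' @export
vs_id <- function() {
  structure(list(kind = "id", dim = 1L, n_factors = 0L), class = "vspec")
}

#' @rdname vs_id
#' @export
vs_diag <- function(dim) {
  dim <- as.integer(dim)
  stopifnot(dim >= 1L)
  structure(list(kind = "diag", dim = dim, n_factors = 0L), class = "vspec")
}

#' @rdname vs_id
#' @export
vs_us2 <- function() {
  structure(list(kind = "us2", dim = 2L, n_factors = 0L), class = "vspec")
}

#' @rdname vs_id
#' @export
vs_rr <- function(dim, n_factors) {
  dim <- as.integer(dim); k <- as.integer(n_factors)
  stopifnot(dim >= 2L, k >= 1L)
  if (k > dim - 1L) stop("n_factors = ", k, " not identifiable with dim = ", dim)
  structure(list(kind = "rr", dim = dim, n_factors = k), class = "vspec")
}

#' @rdname vs_id
#' @export
vs_rr_diag <- function(dim, n_factors) {
  dim <- as.integer(dim); k <- as.integer(n_factors)
  stopifnot(dim >= 2L, k >= 1L)
  if (k > dim - 1L) {
    stop("n_factors = ", k, " not identifiable with dim = ", dim)
  }
  # parameter count must not exceed the unstructured matrix
  if (dim * k - k * (k - 1L) / 2L + dim > dim * (dim + 1L) / 2L) {
    stop("reduced-rank + diagonal structure overparameterized for dim = ", dim)
  }
  structure(list(kind = "rr_diag", dim = dim, n_factors = k), class = "vspec")
}

n_vpar <- function(spec) {
  nl <- spec$dim * spec$n_factors - (spec$n_factors * (spec$n_factors - 1L)) %/% 2L
  switch(spec$kind,
    id = 1L,
    diag = spec$dim,
    us2 = 3L,
    rr = nl,
    rr_diag = nl + spec$dim
  )
}

# free-entry index of Lambda (column-major, upper triangle structurally 0)
lambda_free_idx <- function(p, k) {
  idx <- NULL
  for (h in seq_len(k)) idx <- c(idx, (h - 1L) * p + (h:p))
  idx
}

lambda_from_par <- function(par, p, k) {
  L <- matrix(0, p, k)
  L[lambda_free_idx(p, k)] <- par
  L
}

#' Define a random term for the REML engine
#'
#' A random term couples a variance specification ([vs_id()] and friends)
#' with the factors that index its effects. For a plain term (`vs_id`)
#' give `inner` (one effect per level) or a ready-made design matrix `Z`.
#' For structured terms (`vs_diag`, `vs_us2`, `vs_rr_diag`) give both
#' `inner` (the replicated dimension, e.g. genotype) and `outer` (the
#' structured dimension, e.g. year-site or trait); the effect vector is
#' ordered inner-major so its covariance is `I_q (x) Sigma`.
#'
#' @param name Term label used to retrieve BLUPs and PEV from the fit.
#' @param spec A `"vspec"` object.
#' @param inner Factor of length n (or coercible) indexing replicated levels.
#' @param outer Factor of length n indexing the structured dimension
#'   (required unless `spec` is `vs_id`).
#' @param Z Optional explicit design matrix (n x q) for a `vs_id` term,
#'   e.g. a spatial spline basis in mixed-model form.
#' @return An object of class `"ranef_term"`.
#' @export
ranef <- function(name, spec, inner = NULL, outer = NULL, Z = NULL) {
  stopifnot(inherits(spec, "vspec"))
  if (is.null(Z)) {
    inner <- droplevels(as.factor(inner))
    if (spec$kind != "id") {
      outer <- as.factor(outer)
      if (nlevels(outer) != spec$dim) {
        stop("term '", name, "': outer factor has ", nlevels(outer),
             " levels but spec dimension is ", spec$dim)
      }
    } else if (!is.null(outer)) {
      stop("term '", name, "': outer factor given for vs_id spec")
    }
  } else {
    if (spec$kind != "id") stop("explicit Z only supported for vs_id terms")
    Z <- methods::as(methods::as(Matrix::Matrix(Z, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  }
  structure(list(name = name, spec = spec, inner = inner, outer = outer, Z = Z),
            class = "ranef_term")
}

# Precompute the structural (parameter-independent) pieces of one term.
term_struct <- function(term, n) {
  spec <- term$spec
  if (!is.null(term$Z)) {
    return(list(spec = spec, q = ncol(term$Z), ncol = ncol(term$Z),
                Z = term$Z, labels = colnames(term$Z)))
  }
  inner <- term$inner
  q <- nlevels(inner)
  ii <- as.integer(inner)
  if (spec$kind == "id") {
    Z <- Matrix::sparseMatrix(i = seq_len(n), j = ii, x = 1, dims = c(n, q))
    return(list(spec = spec, q = q, ncol = q, Z = Z, labels = levels(inner)))
  }
  d <- spec$dim
  jj <- as.integer(term$outer)
  if (spec$kind %in% c("diag", "us2")) {
    col <- (ii - 1L) * d + jj
    Z <- Matrix::sparseMatrix(i = seq_len(n), j = col, x = 1, dims = c(n, q * d))
    return(list(spec = spec, q = q, ncol = q * d, Z = Z,
                labels = levels(inner), outer_labels = levels(term$outer)))
  }
  # rr / rr_diag: score columns (inner-major, k per genotype), for
  # rr_diag additionally one lack-of-fit column per cell
  k <- spec$n_factors
  sc_i <- rep(seq_len(n), k)
  sc_j <- as.vector(outer((ii - 1L) * k, seq_len(k), "+"))
  nc <- if (spec$kind == "rr") q * k else q * k + q * d
  st <- list(spec = spec, q = q, ncol = nc,
             sc_i = sc_i, sc_j = sc_j, outer_idx = jj,
             labels = levels(inner), outer_labels = levels(term$outer))
  if (spec$kind == "rr_diag") {
    dl_col <- q * k + (ii - 1L) * d + jj
    st$Zdelta <- Matrix::sparseMatrix(i = seq_len(n), j = dl_col,
                                      x = 1, dims = c(n, nc))
  }
  st
}

PSI_FLOOR <- 1e-8

# Z, G^-1 diagonal/blocks and log|G| for one term at parameter value th.
# need_Z = FALSE skips the (costly) sparse design construction when the
# caller assembles the design from a precomputed skeleton.
term_eval <- function(st, th, n, need_Z = TRUE) {
  spec <- st$spec
  switch(spec$kind,
    id = {
      s2 <- exp(th) + PSI_FLOOR
      list(Z = st$Z, ginv = rep(1 / s2, st$q), ldG = st$q * log(s2),
           vp = list(sigma2 = s2))
    },
    diag = {
      s2 <- exp(th) + PSI_FLOOR
      list(Z = st$Z, ginv = rep(1 / s2, st$q), ldG = st$q * sum(log(s2)),
           vp = list(sigma2 = s2))
    },
    us2 = {
      L <- matrix(c(exp(th[1]), th[2], 0, exp(th[3])), 2, 2)
      Sig <- L %*% t(L)
      Sinv <- chol2inv(t(L))
      ld <- 2 * (th[1] + th[3])
      list(Z = st$Z, ginv_block = Sinv, ldG = st$q * ld,
           vp = list(cov = Sig))
    },
    rr = {
      p <- spec$dim; k <- spec$n_factors
      Lam <- lambda_from_par(th, p, k)
      Zsc <- if (need_Z) {
        Matrix::sparseMatrix(i = st$sc_i, j = st$sc_j,
                             x = as.vector(Lam[st$outer_idx, ]),
                             dims = c(n, st$ncol))
      }
      list(Z = Zsc, ginv = rep(1, st$q * k), ldG = 0,
           vp = list(loadings = Lam))
    },
    rr_diag = {
      p <- spec$dim; k <- spec$n_factors
      nl <- p * k - (k * (k - 1L)) %/% 2L
      Lam <- lambda_from_par(th[seq_len(nl)], p, k)
      psi <- exp(th[nl + seq_len(p)]) + PSI_FLOOR
      Z <- if (need_Z) {
        Matrix::sparseMatrix(i = st$sc_i, j = st$sc_j,
                             x = as.vector(Lam[st$outer_idx, ]),
                             dims = c(n, st$ncol)) + st$Zdelta
      }
      list(Z = Z,
           ginv = c(rep(1, st$q * k), rep(1 / psi, st$q)),
           ldG = st$q * sum(log(psi)),
           vp = list(loadings = Lam, psi = psi))
    })
}

# assemble block-diagonal G^-1 for all terms (diagonal except us2 blocks)
assemble_ginv <- function(evs, sts) {
  blocks <- mapply(function(ev, st) {
    if (!is.null(ev$ginv_block)) {
      Matrix::kronecker(Matrix::Diagonal(st$q), ev$ginv_block)
    } else {
      Matrix::Diagonal(x = ev$ginv)
    }
  }, evs, sts, SIMPLIFY = FALSE)
  if (length(blocks) == 1L) blocks[[1]] else Matrix::bdiag(blocks)
}

#' Fit a Gaussian linear mixed model by REML
#'
#' Restricted maximum likelihood with pluggable covariance structures and
#' either weighted-diagonal residuals (`var(e) = sigma2 / w`) or an
#' unstructured 2x2 residual block per group (bivariate models). Fixed
#' effects are absorbed through the mixed-model equations; variance
#' parameters are optimized by quasi-Newton on unconstrained scales.
#'
#' @param y Numeric response vector.
#' @param X Fixed-effects design matrix (full column rank).
#' @param terms List of [ranef()] terms.
#' @param weights Positive weights, `var(e) = sigma2 / w` (default 1).
#' @param residual `"weighted"` (default) or a list
#'   `list(kind = "us2", group = <factor>, slot = <1/2 index>)` for a 2x2
#'   unstructured residual per group (each group must contain one
#'   observation per slot).
#' @param sigma2_fixed Optionally fix the residual `sigma2` (e.g. at 1 in
#'   a two-stage analysis); default `NULL` estimates it.
#' @param start Optional named list of starting values per term
#'   (transformed scale), or a full numeric parameter vector.
#' @param control List: `maxit` (default 400), `factr` (default 1e7),
#'   `ndeps` step for finite differences (default 1e-4).
#' @return An object of class `"reml_fit"`: fixed estimates (`beta`,
#'   `vcov_beta`), variance parameters (`vp`, one entry per term plus
#'   `residual`), BLUPs (`blup`), REML and full log-likelihoods, `bic`,
#'   `n_obs`, `n_params`, `converged`, and a `pev()` accessor for
#'   prediction-error-variance blocks.
#' @export
reml_fit <- function(y, X, terms, weights = NULL,
                     residual = "weighted", sigma2_fixed = NULL,
                     start = NULL, control = list()) {
  y <- as.numeric(y)
  n <- length(y)
  if (any(!is.finite(y))) stop("non-finite values in response")
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(ncol(X)))
  if (nrow(X) != n) stop("X rows do not match response length")
  if (qr(X)$rank < ncol(X)) stop("fixed design is rank deficient")
  pfix <- ncol(X)
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights <= 0) || any(!is.finite(weights))) stop("weights must be positive")
  if (inherits(terms, "ranef_term")) terms <- list(terms)
  stopifnot(length(terms) >= 1L)
  names(terms) <- vapply(terms, `[[`, "", "name")

  ctrl <- list(maxit = 400L, factr = 1e7, pgtol = 1e-5, ndeps = 1e-6)
  ctrl[names(control)] <- control

  sts <- lapply(terms, term_struct, n = n)
  npar_terms <- unname(vapply(sts, function(s) n_vpar(s$spec), 1L))
  off <- cumsum(c(0L, npar_terms))

  res_kind <- if (is.list(residual)) residual$kind else residual
  if (res_kind == "us2") {
    grp <- as.factor(residual$group)
    slot <- as.integer(residual$slot)
    if (!all(tabulate(grp) == 2L)) stop("us2 residual: each group needs exactly 2 observations")
    o <- order(grp, slot)
    if (any(slot[o] != rep(1:2, nlevels(grp)))) {
      stop("us2 residual: each group needs one observation per slot")
    }
    i1 <- o[seq(1, n, by = 2)]; i2 <- o[seq(2, n, by = 2)]
    ng <- nlevels(grp)
    npar_res <- 3L
  } else if (res_kind == "weighted_diag") {
    # var(e_i) = sigma2 / w_i + psi_{outer(i)}: a random term with one
    # level per observation folded into the residual (they are confounded)
    res_outer <- as.factor(residual$outer)
    d_res <- nlevels(res_outer)
    res_idx <- as.integer(res_outer)
    npar_res <- d_res + (if (is.null(sigma2_fixed)) 1L else 0L)
  } else if (res_kind == "weighted") {
    npar_res <- if (is.null(sigma2_fixed)) 1L else 0L
  } else {
    stop("unknown residual kind: ", res_kind)
  }
  npar <- off[length(off)] + npar_res

  Xs <- methods::as(methods::as(Matrix::Matrix(X, sparse = TRUE),
                                "generalMatrix"), "CsparseMatrix")

  res_eval <- function(par) {
    if (res_kind == "weighted_diag") {
      th <- par[off[length(off)] + seq_len(npar_res)]
      psi <- exp(th[seq_len(d_res)]) + PSI_FLOOR
      s2 <- if (is.null(sigma2_fixed)) exp(th[npar_res]) else sigma2_fixed
      rv <- s2 / weights + psi[res_idx]
      list(rinv = 1 / rv, ldR = sum(log(rv)),
           vp = list(sigma2 = s2, psi = stats::setNames(psi, levels(res_outer)),
                     var_obs = rv))
    } else {
      s2 <- if (is.null(sigma2_fixed)) exp(par[npar]) else sigma2_fixed
      list(rinv = weights / s2, ldR = n * log(s2) - sum(log(weights)),
           vp = list(sigma2 = s2))
    }
  }

  # Fast path (diagonal residual, diagonal G^-1): one sparse skeleton
  # M = [X Z] whose numeric slot is updated in place per evaluation, with
  # the symbolic Cholesky analysis of the coefficient matrix reused.
  fast <- res_kind %in% c("weighted", "weighted_diag") &&
    !any(vapply(sts, function(s) s$spec$kind, "") == "us2")
  if (fast) {
    # augmented design A = [ sqrt(Rinv) X , sqrt(Rinv) Z ; 0 , sqrt(Ginv) ]
    # so that crossprod(A) is the full MME coefficient matrix; only the
    # numeric slot of A changes between evaluations.
    xtr <- Matrix::mat2triplet(Xs)
    ti <- tj <- tv <- list(); dyn <- vector("list", length(sts))
    zoff <- 0L; pos <- 0L
    for (t in seq_along(sts)) {
      st <- sts[[t]]
      if (st$spec$kind %in% c("rr", "rr_diag")) {
        nsc <- length(st$sc_i)
        dyn[[t]] <- pos + seq_len(nsc)
        if (st$spec$kind == "rr") {
          ti[[t]] <- st$sc_i; tj[[t]] <- zoff + st$sc_j
          tv[[t]] <- rep(1, nsc)
        } else {
          trd <- Matrix::mat2triplet(st$Zdelta)
          ti[[t]] <- c(st$sc_i, trd$i); tj[[t]] <- zoff + c(st$sc_j, trd$j)
          tv[[t]] <- c(rep(1, nsc), trd$x)
        }
      } else {
        tr <- Matrix::mat2triplet(st$Z)
        ti[[t]] <- tr$i; tj[[t]] <- zoff + tr$j; tv[[t]] <- tr$x
      }
      pos <- pos + length(ti[[t]])
      zoff <- zoff + st$ncol
    }
    qtot <- zoff
    z_i <- unlist(ti); z_j <- unlist(tj); zvals0 <- unlist(tv)
    aug_i <- c(xtr$i, z_i, n + seq_len(qtot))
    aug_j <- c(xtr$j, pfix + z_j, pfix + seq_len(qtot))
    Acode <- Matrix::sparseMatrix(i = aug_i, j = aug_j,
                                  x = seq_along(aug_i),
                                  dims = c(n + qtot, pfix + qtot))
    aperm <- as.integer(Acode@x)
    Ask <- Acode
    nxv <- length(xtr$x); nzv <- length(zvals0)
    chsym <- NULL
    yaug <- numeric(n + qtot)
  }

  eval_fast <- function(par, keep = FALSE) {
    evs <- lapply(seq_along(sts), function(t) {
      term_eval(sts[[t]], par[off[t] + seq_len(npar_terms[t])], n,
                need_Z = FALSE)
    })
    zvals <- zvals0
    for (t in seq_along(sts)) {
      if (!is.null(dyn[[t]])) {
        zvals[dyn[[t]]] <- as.vector(evs[[t]]$vp$loadings[sts[[t]]$outer_idx, ])
      }
    }
    re <- res_eval(par)
    sr <- sqrt(re$rinv)
    ginv <- unlist(lapply(evs, `[[`, "ginv"), use.names = FALSE)
    ldG <- sum(vapply(evs, `[[`, 0, "ldG"))
    vals <- c(xtr$x * sr[xtr$i], zvals * sr[z_i], sqrt(ginv))
    Ask@x <- vals[aperm]
    C <- Matrix::crossprod(Ask)
    yaug[seq_len(n)] <- sr * y
    rhs <- as.vector(Matrix::crossprod(Ask, yaug))
    ch <- tryCatch(suppressWarnings({
      if (is.null(chsym)) {
        chsym <<- Matrix::Cholesky(C, LDL = FALSE, perm = TRUE)
      } else {
        Matrix::.updateCHMfactor(chsym, C, mult = 0)
      }
    }), error = function(e) NULL)
    if (is.null(ch)) return(if (keep) NULL else Inf)
    ldC <- 2 * as.numeric(Matrix::determinant(ch, sqrt = TRUE)$modulus)
    b <- as.vector(Matrix::solve(ch, rhs, system = "A"))
    ytRiy <- sum(re$rinv * y^2)
    quad <- ytRiy - sum(rhs * b)
    ll <- -0.5 * ((n - pfix) * log(2 * pi) + re$ldR + ldG + ldC + quad)
    if (!is.finite(ll)) return(if (keep) NULL else Inf)
    if (!keep) return(-ll)
    C22 <- C[-seq_len(pfix), -seq_len(pfix)]
    ch22 <- Matrix::Cholesky(Matrix::forceSymmetric(C22), LDL = FALSE, perm = TRUE)
    ldC22 <- 2 * as.numeric(Matrix::determinant(ch22, sqrt = TRUE)$modulus)
    list(ll = ll, b = b, ch = ch, ldXVX = ldC - ldC22,
         evs = evs, res_vp = re$vp)
  }

  eval_slow <- function(par, keep = FALSE) {
    evs <- lapply(seq_along(sts), function(t) {
      term_eval(sts[[t]], par[off[t] + seq_len(npar_terms[t])], n)
    })
    Zall <- do.call(cbind, lapply(evs, `[[`, "Z"))
    Ginv <- assemble_ginv(evs, sts)
    ldG <- sum(vapply(evs, `[[`, 0, "ldG"))

    if (res_kind == "us2") {
      th <- par[npar - 2:0]
      Lr <- matrix(c(exp(th[1]), th[2], 0, exp(th[3])), 2, 2)
      Sig_e <- Lr %*% t(Lr)
      Si <- chol2inv(t(Lr))
      Rinv <- Matrix::sparseMatrix(
        i = c(i1, i2, i1, i2), j = c(i1, i2, i2, i1),
        x = c(rep(Si[1, 1], ng), rep(Si[2, 2], ng),
              rep(Si[1, 2], 2 * ng)), dims = c(n, n))
      ldR <- ng * 2 * (th[1] + th[3])
      res_vp <- list(cov = Sig_e)
    } else if (res_kind == "weighted_diag") {
      th <- par[off[length(off)] + seq_len(npar_res)]
      psi <- exp(th[seq_len(d_res)]) + PSI_FLOOR
      s2 <- if (is.null(sigma2_fixed)) exp(th[npar_res]) else sigma2_fixed
      rv <- s2 / weights + psi[res_idx]
      Rinv <- Matrix::Diagonal(x = 1 / rv)
      ldR <- sum(log(rv))
      res_vp <- list(sigma2 = s2, psi = stats::setNames(psi, levels(res_outer)),
                     var_obs = rv)
    } else {
      s2 <- if (is.null(sigma2_fixed)) exp(par[npar]) else sigma2_fixed
      Rinv <- Matrix::Diagonal(x = weights / s2)
      ldR <- n * log(s2) - sum(log(weights))
      res_vp <- list(sigma2 = s2)
    }

    XtRi <- Matrix::crossprod(Xs, Rinv)
    ZtRi <- Matrix::crossprod(Zall, Rinv)
    C11 <- XtRi %*% Xs
    C12 <- XtRi %*% Zall
    C22 <- ZtRi %*% Zall + Ginv
    C <- rbind(cbind(C11, C12), cbind(Matrix::t(C12), C22))
    rhs <- c(as.vector(XtRi %*% y), as.vector(ZtRi %*% y))
    ch <- tryCatch(suppressWarnings(
      Matrix::Cholesky(Matrix::forceSymmetric(C), LDL = FALSE, perm = TRUE)),
      error = function(e) NULL)
    if (is.null(ch)) return(if (keep) NULL else Inf)
    ldC <- 2 * as.numeric(Matrix::determinant(ch, sqrt = TRUE)$modulus)
    b <- as.vector(Matrix::solve(ch, rhs, system = "A"))
    ytRiy <- as.numeric(Matrix::crossprod(y, Rinv %*% y))
    quad <- ytRiy - sum(rhs * b)
    ll <- -0.5 * ((n - pfix) * log(2 * pi) + ldR + ldG + ldC + quad)
    if (!is.finite(ll)) return(if (keep) NULL else Inf)
    if (!keep) return(-ll)
    ch22 <- Matrix::Cholesky(Matrix::forceSymmetric(C22), LDL = FALSE, perm = TRUE)
    ldC22 <- 2 * as.numeric(Matrix::determinant(ch22, sqrt = TRUE)$modulus)
    list(ll = ll, b = b, ch = ch, ldXVX = ldC - ldC22,
         evs = evs, res_vp = res_vp)
  }

  eval_model <- if (fast) eval_fast else eval_slow

  par0 <- init_par(start, y, X, weights, sts, npar_terms, off, npar,
                   npar_res, res_kind, sigma2_fixed)

  # scale-aware box bounds: log-variances within [log v0 - 23, log v0 + 16]
  # (keeps boundary estimates from crawling indefinitely on the log scale),
  # raw loading / covariance parameters within +- 10 sd(y)
  v0b <- log(max(stats::var(y), 1e-12))
  lower <- rep(-Inf, npar); upper <- rep(Inf, npar)
  bnd_raw <- 10 * sqrt(max(stats::var(y), 1e-12))
  for (t in seq_along(sts)) {
    spec <- sts[[t]]$spec
    idx <- off[t] + seq_len(npar_terms[t])
    nl <- spec$dim * spec$n_factors - (spec$n_factors * (spec$n_factors - 1L)) %/% 2L
    if (spec$kind %in% c("id", "diag")) {
      lower[idx] <- v0b - 23; upper[idx] <- v0b + 16
    } else if (spec$kind == "us2") {
      lower[idx] <- c(v0b / 2 - 12, -bnd_raw, v0b / 2 - 12)
      upper[idx] <- c(v0b / 2 + 8, bnd_raw, v0b / 2 + 8)
    } else { # rr / rr_diag
      lower[idx[seq_len(nl)]] <- -bnd_raw
      upper[idx[seq_len(nl)]] <- bnd_raw
      if (spec$kind == "rr_diag") {
        lower[idx[nl + seq_len(spec$dim)]] <- v0b - 23
        upper[idx[nl + seq_len(spec$dim)]] <- v0b + 16
      }
    }
  }
  if (npar_res > 0) {
    ridx <- npar - rev(seq_len(npar_res)) + 1L
    if (res_kind == "us2") {
      lower[ridx] <- c(v0b / 2 - 12, -bnd_raw, v0b / 2 - 12)
      upper[ridx] <- c(v0b / 2 + 8, bnd_raw, v0b / 2 + 8)
    } else {
      lower[ridx] <- v0b - 23; upper[ridx] <- v0b + 16
    }
  }
  par0 <- pmin(pmax(par0, lower), upper)

  obj <- function(p) {
    v <- eval_model(p)
    if (!is.finite(v)) 1e10 else v
  }
  # forward-difference gradient with a memoized base value: halves the
  # likelihood evaluations relative to optim's internal central scheme
  last <- new.env(parent = emptyenv())
  obj_m <- function(p) {
    v <- obj(p)
    last$p <- p; last$v <- v
    v
  }
  grad <- function(p) {
    f0 <- if (!is.null(last$p) && identical(p, last$p)) last$v else obj(p)
    h <- ctrl$ndeps
    vapply(seq_along(p), function(j) {
      pj <- p; pj[j] <- pj[j] + h
      (obj(pj) - f0) / h
    }, 0)
  }
  opt <- stats::optim(par0, obj_m, grad, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = ctrl$maxit, factr = ctrl$factr,
                                     pgtol = ctrl$pgtol))
  # a restart with fresh quasi-Newton memory resolves most maxit stops
  for (try in 1:2) {
    if (opt$convergence == 0L) break
    opt2 <- stats::optim(opt$par, obj_m, grad, method = "L-BFGS-B",
                         lower = lower, upper = upper,
                         control = list(maxit = ctrl$maxit, factr = ctrl$factr,
                                        pgtol = ctrl$pgtol))
    if (opt2$value <= opt$value) opt <- opt2 else break
  }
  # polish with central differences (O(h^2) accurate) for sharp optima
  grad_c <- function(p) {
    h <- 1e-5
    vapply(seq_along(p), function(j) {
      pp <- pm <- p
      pp[j] <- pp[j] + h; pm[j] <- pm[j] - h
      (obj(pp) - obj(pm)) / (2 * h)
    }, 0)
  }
  optp <- stats::optim(opt$par, obj, grad_c, method = "L-BFGS-B",
                       lower = lower, upper = upper,
                       control = list(maxit = 50L, factr = 10,
                                      pgtol = ctrl$pgtol / 100))
  if (optp$value <= opt$value) {
    optp$convergence <- min(optp$convergence, opt$convergence)
    opt <- optp
  }
  fin <- eval_model(opt$par, keep = TRUE)
  if (is.null(fin)) stop("REML likelihood not evaluable at optimizer solution")
  converged <- opt$convergence == 0L && is.finite(fin$ll)

  beta <- fin$b[seq_len(pfix)]
  names(beta) <- colnames(X)
  # split BLUPs per term
  col_off <- pfix + cumsum(c(0L, vapply(sts, `[[`, 1L, "ncol")))
  blup <- vp <- vector("list", length(sts))
  names(blup) <- names(vp) <- names(terms)
  for (t in seq_along(sts)) {
    st <- sts[[t]]; u <- fin$b[col_off[t] + seq_len(st$ncol)]
    vp[[t]] <- fin$evs[[t]]$vp
    blup[[t]] <- reshape_blup(st, u)
  }
  vp$residual <- fin$res_vp

  ch <- fin$ch
  mme_dim <- length(fin$b)
  solve_block <- function(cols) {
    E <- Matrix::sparseMatrix(i = cols, j = seq_along(cols), x = 1,
                              dims = c(mme_dim, length(cols)))
    as.matrix(Matrix::solve(ch, E, system = "A")[cols, , drop = FALSE])
  }
  vcov_beta <- solve_block(seq_len(pfix))
  dimnames(vcov_beta) <- list(colnames(X), colnames(X))

  loglik_full <- fin$ll + 0.5 * fin$ldXVX - 0.5 * pfix * log(2 * pi)
  n_params <- npar + pfix
  bic <- -2 * loglik_full + n_params * log(n)

  fit <- list(beta = beta, vcov_beta = vcov_beta, vp = vp, blup = blup,
              loglik_reml = fin$ll, loglik_full = loglik_full, bic = bic,
              n_obs = n, n_params = n_params, n_varpar = npar,
              converged = converged, par = opt$par, objective = obj,
              optim = opt[c("convergence", "counts", "message")],
              term_info = lapply(sts, function(s) s[c("spec", "q", "ncol", "labels")]))
  fit$pev <- function(term, part = c("all", "scores", "delta")) {
    part <- match.arg(part)
    t <- match(term, names(terms))
    if (is.na(t)) stop("unknown term: ", term)
    st <- sts[[t]]
    cols <- col_off[t] + seq_len(st$ncol)
    if (st$spec$kind == "rr_diag" && part != "all") {
      k <- st$spec$n_factors
      cols <- if (part == "scores") cols[seq_len(st$q * k)] else cols[-seq_len(st$q * k)]
    }
    solve_block(cols)
  }
  class(fit) <- "reml_fit"
  fit
}

reshape_blup <- function(st, u) {
  spec <- st$spec
  if (spec$kind == "id") {
    names(u) <- st$labels
    return(u)
  }
  if (spec$kind %in% c("diag", "us2")) {
    m <- matrix(u, nrow = st$q, ncol = spec$dim, byrow = TRUE,
                dimnames = list(st$labels, st$outer_labels))
    return(m)
  }
  k <- spec$n_factors
  scores <- matrix(u[seq_len(st$q * k)], nrow = st$q, byrow = TRUE,
                   dimnames = list(st$labels, paste0("f", seq_len(k))))
  if (spec$kind == "rr") return(list(scores = scores))
  delta <- matrix(u[-seq_len(st$q * k)], nrow = st$q, byrow = TRUE,
                  dimnames = list(st$labels, st$outer_labels))
  list(scores = scores, delta = delta)
}

init_par <- function(start, y, X, weights, sts, npar_terms, off, npar,
                     npar_res, res_kind, sigma2_fixed) {
  if (is.numeric(start) && length(start) == npar) return(start)
  fit0 <- stats::lm.wfit(X, y, weights)
  v0 <- max(sum(weights * fit0$residuals^2) / max(fit0$df.residual, 1), 1e-6)
  share <- v0 / (length(sts) + 1)
  par <- numeric(npar)
  for (t in seq_along(sts)) {
    spec <- sts[[t]]$spec
    idx <- off[t] + seq_len(npar_terms[t])
    nl <- spec$dim * spec$n_factors - (spec$n_factors * (spec$n_factors - 1L)) %/% 2L
    p0 <- switch(spec$kind,
      id = log(share),
      diag = rep(log(share), spec$dim),
      us2 = c(log(sqrt(share)), 0, log(sqrt(share))),
      rr = rep(sqrt(share / spec$n_factors), nl),
      rr_diag = c(rep(sqrt(share / spec$n_factors), nl),
                  rep(log(share), spec$dim)))
    if (is.list(start) && !is.null(start[[names(sts)[t]]])) p0 <- start[[names(sts)[t]]]
    par[idx] <- p0
  }
  if (npar_res > 0) {
    res0 <- switch(res_kind,
      us2 = c(log(sqrt(v0)), 0, log(sqrt(v0))),
      weighted_diag = c(rep(log(share), npar_res - is.null(sigma2_fixed)),
                        if (is.null(sigma2_fixed)) log(share)),
      weighted = log(share))
    if (is.list(start) && !is.null(start$residual)) res0 <- start$residual
    par[npar - rev(seq_len(npar_res)) + 1L] <- res0
  }
  par
}

#' @export
print.reml_fit <- function(x, ...) {
  cat("REML fit:", x$n_obs, "observations,", length(x$beta), "fixed effects,",
      x$n_varpar, "variance parameters\n")
  cat(sprintf("  logLik (REML) %.3f | logLik (full) %.3f | BIC %.2f | %s\n",
              x$loglik_reml, x$loglik_full, x$bic,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Full-likelihood information criteria of a REML fit
#'
#' The BIC is computed from the full log-likelihood (restricted
#' log-likelihood plus the fixed-effect profile term
#' `0.5 log|X'V^-1 X| - (p/2) log(2 pi)`), so models differing in their
#' fixed effects remain comparable. The parameter count is the number of
#' estimated variance parameters plus fixed-effect coefficients, and the
#' sample size is the number of observations.
#'
#' @param fit A [reml_fit()] result.
#' @return List with `loglik_full`, `bic`, and `reliable` (FALSE when the
#'   optimizer did not converge).
#' @export
information_criteria <- function(fit) {
  stopifnot(inherits(fit, "reml_fit"))
  if (!fit$converged) {
    warning("information criteria from an unconverged fit are unreliable")
  }
  list(loglik_full = fit$loglik_full, bic = fit$bic, reliable = fit$converged)
}

#' Serialize the parameters of a REML fit to JSON
#'
#' @param fit A [reml_fit()] result.
#' @return A JSON string (variance parameters, log-likelihoods, BIC).
#' @export
reml_to_json <- function(fit) {
  stopifnot(inherits(fit, "reml_fit"))
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("jsonlite is required for serialization")
  }
  jsonlite::toJSON(list(variance_params = fit$vp, beta = as.list(fit$beta),
                        loglik_reml = fit$loglik_reml,
                        loglik_full = fit$loglik_full, bic = fit$bic,
                        n_obs = fit$n_obs, n_params = fit$n_params,
                        converged = fit$converged),
                   auto_unbox = TRUE, digits = NA)
}
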