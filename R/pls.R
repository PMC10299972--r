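# Univariate partial least squares regression (PLS1, NIPALS).
#
# Small self-contained implementation for phenomic prediction from a
# handful of collinear HTFP traits: predictors are centered and scaled
# with training-set statistics, the response centered.

#' Fit a PLS1 regression
#'
#' NIPALS partial least squares with a single response. Predictors are
#' standardized (center/scale) with the training data; the returned
#' coefficients are on the original predictor scale.
#'
#' @param X Numeric matrix (n x p) of predictors.
#' @param y Numeric response vector.
#' @param ncomp Number of latent components (capped at `min(n-1, p)`).
#' @param scale Scale predictors to unit variance (default TRUE).
#' @return Object of class `"pls1"`: `coef_std` (coefficients for
#'   standardized predictors — the feature scores), `beta`, `intercept`,
#'   loading weights `W`, loadings `P`, component coefficients `q`,
#'   `ncomp`.
#' @export
pls_fit <- function(X, y, ncomp, scale = TRUE) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), ncomp >= 1)
  n <- nrow(X); p <- ncol(X)
  ncomp <- min(ncomp, n - 1L, p)
  xm <- colMeans(X)
  xs <- if (scale) apply(X, 2, stats::sd) else rep(1, p)
  xs[xs < 1e-12] <- 1
  E <- sweep(sweep(X, 2, xm), 2, xs, "/")
  ym <- mean(y)
  f <- y - ym
  W <- P <- matrix(0, p, ncomp)
  qv <- numeric(ncomp)
  used <- 0L
  for (h in seq_len(ncomp)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    tt <- drop(E %*% w)
    t2 <- sum(tt^2)
    if (t2 < 1e-12) break
    ph <- drop(crossprod(E, tt)) / t2
    qh <- sum(f * tt) / t2
    E <- E - tcrossprod(tt, ph)
    f <- f - qh * tt
    W[, h] <- w; P[, h] <- ph; qv[h] <- qh
    used <- h
  }
  if (used == 0L) stop("response is orthogonal to all predictors")
  W <- W[, seq_len(used), drop = FALSE]
  P <- P[, seq_len(used), drop = FALSE]
  qv <- qv[seq_len(used)]
  coef_std <- drop(W %*% solve(crossprod(P, W), qv))
  beta <- coef_std / xs
  structure(list(coef_std = stats::setNames(coef_std, colnames(X)),
                 beta = stats::setNames(beta, colnames(X)),
                 intercept = ym - sum(beta * xm),
                 W = W, P = P, q = qv, ncomp = used,
                 xmean = xm, xsd = xs, ymean = ym,
                 features = colnames(X)),
            class = "pls1")
}

#' @export
predict.pls1 <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!is.null(object$features) && !is.null(colnames(X))) {
    X <- X[, object$features, drop = FALSE]
  }
  drop(X %*% object$beta) + object$intercept
}

#' @export
print.pls1 <- function(x, ...) {
  cat("PLS1 fit:", x$ncomp, "component(s),", length(x$beta), "predictors\n")
  invisible(x)
}
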