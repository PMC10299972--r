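# FAST post-processing of a factor-analytic fit: rotation of the
# loadings to principal axes and extraction of overall performance (OP)
# and stability (RMSD) per genotype.

#' Rotate factor loadings to principal axes
#'
#' Rotates the environment loadings so that `Lambda' Lambda` is diagonal
#' with non-increasing diagonal (singular-value form), fixes the sign of
#' each factor so its loading sum is positive, and counter-rotates the
#' genotype scores so the fitted GxE effects `Lambda F'` are unchanged.
#'
#' @param fa A `"fa_fit"` with at least one factor.
#' @return The rotated `"fa_fit"` (`rotated = TRUE`).
#' @export
rotate_loadings <- function(fa) {
  stopifnot(inherits(fa, "fa_fit"))
  k <- ncol(fa$loadings)
  if (is.null(k) || k < 1) stop("rotation needs at least one factor")
  sv <- svd(fa$loadings)
  L <- sv$u %*% diag(sv$d, k, k)
  F <- fa$scores %*% sv$v
  for (h in seq_len(k)) {
    if (sum(L[, h]) < 0) {
      L[, h] <- -L[, h]
      F[, h] <- -F[, h]
    }
  }
  dimnames(L) <- dimnames(fa$loadings)
  dimnames(F) <- dimnames(fa$scores)
  fa$loadings <- L
  fa$scores <- F
  fa$rotated <- TRUE
  fa
}

#' Overall performance and stability (FAST indices)
#'
#' From a rotated factor-analytic fit: overall performance
#' `OP_i = lbar_1 * f_i1` (mean first-factor loading times first genotype
#' score), optionally re-centered by the mean fixed-effect year-site
#' intercept so OP is on the trait scale (t/ha for yield); stability
#' `RMSD_i = sqrt(mean_j (sum_{h>=2} lambda_jh f_ih)^2)`, the
#' root-mean-squared deviation of the higher-factor GxE effects over the
#' fitted population of environments. Low RMSD means high stability;
#' with a single factor RMSD is identically zero.
#'
#' @param fa A rotated `"fa_fit"` (see [rotate_loadings()]).
#' @param include_mean Add the mean year-site intercept to OP
#'   (default TRUE).
#' @return data.frame of class `"stability_result"`: `genotype`, `op`,
#'   `rmsd`.
#' @export
op_rmsd <- function(fa, include_mean = TRUE) {
  stopifnot(inherits(fa, "fa_fit"))
  if (!isTRUE(fa$rotated)) stop("loadings must be rotated first (rotate_loadings)")
  L <- fa$loadings
  F <- fa$scores
  k <- ncol(L)
  op <- mean(L[, 1]) * F[, 1]
  if (include_mean) {
    if (is.null(fa$env_intercepts)) stop("fit has no environment intercepts")
    op <- op + mean(fa$env_intercepts)
  }
  rmsd <- if (k > 1) {
    sqrt(rowMeans((F[, -1, drop = FALSE] %*% t(L[, -1, drop = FALSE]))^2))
  } else {
    rep(0, nrow(F))
  }
  out <- data.frame(genotype = rownames(F), op = as.numeric(op),
                    rmsd = as.numeric(rmsd), row.names = NULL,
                    stringsAsFactors = FALSE)
  class(out) <- c("stability_result", "data.frame")
  out
}
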