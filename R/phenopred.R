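# Phenomic prediction of target traits from intermediate HTFP traits:
# preprocessing rules, cross-validation schemes with unseen genotypes
# and/or environments, hyperparameter tuning, and feature importance for
# PLS and random-forest learners.

meta_cols <- c("genotype", "year_site", "response")

feature_names <- function(features) {
  setdiff(names(features), meta_cols)
}

#' Map breeder decision labels to the ordinal selection scale
#'
#' `selected` -> 3, `sister_selected` -> 2, `repeated` -> 1,
#' `sister_repeated` -> 0, `discarded` -> -1.
#'
#' @param labels Character vector of decision labels.
#' @return Integer vector on the ordinal scale.
#' @export
decision_to_ordinal <- function(labels) {
  map <- c(selected = 3, sister_selected = 2, repeated = 1,
           sister_repeated = 0, discarded = -1)
  bad <- setdiff(unique(labels), names(map))
  if (length(bad)) stop("unknown decision label(s): ", paste(bad, collapse = ", "))
  unname(map[labels])
}

#' Preprocess a feature table for a prediction task
#'
#' Applies the task-specific filters: for the yield task, rows with
#' `n_tiller > 8000` are removed (a plausibility bound on tiller counts);
#' for every task, rows with missing dose-response (C) traits
#' (`r_max`, `T_min`, `lrc` — missing when the upstream curve fit failed
#' to converge) and rows with a missing response are removed. For the
#' decision task a character response is mapped to the ordinal scale
#' via [decision_to_ordinal()].
#'
#' @param features data.frame with meta columns (`genotype`, optionally
#'   `year_site`), feature columns, and a `response` column.
#' @param task One of `"yield"`, `"op"`, `"rmsd"`, `"protein"`,
#'   `"decision"`.
#' @return Filtered data.frame (attribute `"task"` set).
#' @export
preprocess_features <- function(features,
                                task = c("yield", "op", "rmsd", "protein",
                                         "decision")) {
  task <- match.arg(task)
  stopifnot("response" %in% names(features))
  if (task == "decision" && !is.numeric(features$response)) {
    features$response <- decision_to_ordinal(as.character(features$response))
  }
  if (task == "yield" && "n_tiller" %in% names(features)) {
    features <- features[is.na(features$n_tiller) | features$n_tiller <= 8000, ]
  }
  c_traits <- intersect(c("r_max", "T_min", "lrc"), names(features))
  if (length(c_traits)) {
    ok <- stats::complete.cases(features[, c_traits, drop = FALSE])
    features <- features[ok, ]
  }
  features <- features[!is.na(features$response), ]
  rownames(features) <- NULL
  attr(features, "task") <- task
  features
}

#' Define a cross-validation scheme
#'
#' @param kind `"unseen_E"` (leave one year-site out), `"unseen_G"`
#'   (leave one genotype out), `"unseen_GE"` (one fold per observed
#'   genotype x year-site cell, training excludes the whole year-site
#'   and the whole genotype), or `"kfold"` (repeated random k-fold).
#' @param k Number of folds for `"kfold"`.
#' @param repeats Number of repeats for `"kfold"`.
#' @return Object of class `"cv_scheme"`.
#' @export
cv_scheme <- function(kind = c("unseen_E", "unseen_G", "unseen_GE", "kfold"),
                      k = 8, repeats = 5) {
  kind <- match.arg(kind)
  structure(list(kind = kind, k = as.integer(k),
                 repeats = as.integer(repeats)), class = "cv_scheme")
}

#' Build cross-validation folds
#'
#' @param meta data.frame with `genotype` and (where required)
#'   `year_site` columns, one row per observation.
#' @param scheme A [cv_scheme()].
#' @param seed Seed for the random `"kfold"` scheme.
#' @return List of folds, each `list(train = <indices>, test = <indices>)`.
#' @export
make_folds <- function(meta, scheme, seed = 1) {
  stopifnot(inherits(scheme, "cv_scheme"))
  n <- nrow(meta)
  idx <- seq_len(n)
  if (scheme$kind == "unseen_E") {
    stopifnot("year_site" %in% names(meta))
    lapply(unique(meta$year_site), function(e) {
      list(train = idx[meta$year_site != e], test = idx[meta$year_site == e])
    })
  } else if (scheme$kind == "unseen_G") {
    stopifnot("genotype" %in% names(meta))
    lapply(unique(meta$genotype), function(g) {
      list(train = idx[meta$genotype != g], test = idx[meta$genotype == g])
    })
  } else if (scheme$kind == "unseen_GE") {
    stopifnot(all(c("genotype", "year_site") %in% names(meta)))
    lapply(idx, function(r) {
      list(train = idx[meta$genotype != meta$genotype[r] &
                         meta$year_site != meta$year_site[r]],
           test = r)
    })
  } else {
    set.seed(seed)
    strat <- if ("year_site" %in% names(meta)) meta$year_site else rep(1, n)
    folds <- list()
    for (r in seq_len(scheme$repeats)) {
      fold_id <- integer(n)
      for (s in unique(strat)) {
        rows <- sample(idx[strat == s])
        fold_id[rows] <- rep_len(seq_len(scheme$k), length(rows))
      }
      folds <- c(folds, lapply(seq_len(scheme$k), function(f) {
        list(train = idx[fold_id != f], test = idx[fold_id == f])
      }))
    }
    folds
  }
}

#' Tune the number of PLS components
#'
#' Chooses `ncomp` once per task by k-fold cross-validated RMSE over all
#' data points.
#'
#' @param features Preprocessed feature table (see
#'   [preprocess_features()]).
#' @param ncomp_max Largest number of components tried.
#' @param k Folds of the tuning CV (default 10).
#' @param seed Seed for fold assignment.
#' @return List: `ncomp` (selected), `rmse` (per candidate).
#' @export
tune_pls <- function(features, ncomp_max = 10, k = 10, seed = 1) {
  fx <- feature_names(features)
  X <- as.matrix(features[, fx, drop = FALSE])
  y <- features$response
  n <- nrow(X)
  ncomp_max <- min(ncomp_max, ncol(X), n - ceiling(n / k) - 1L)
  set.seed(seed)
  fold_id <- rep_len(seq_len(k), n)[sample(n)]
  press <- numeric(ncomp_max)
  for (f in seq_len(k)) {
    tr <- fold_id != f
    fit <- pls_fit(X[tr, , drop = FALSE], y[tr], ncomp_max)
    for (nc in seq_len(ncomp_max)) {
      W <- fit$W[, seq_len(min(nc, fit$ncomp)), drop = FALSE]
      P <- fit$P[, seq_len(min(nc, fit$ncomp)), drop = FALSE]
      qv <- fit$q[seq_len(min(nc, fit$ncomp))]
      cs <- drop(W %*% solve(crossprod(P, W), qv))
      beta <- cs / fit$xsd
      pred <- drop(X[!tr, , drop = FALSE] %*% beta) +
        (fit$ymean - sum(beta * fit$xmean))
      press[nc] <- press[nc] + sum((y[!tr] - pred)^2)
    }
  }
  rmse <- sqrt(press / n)
  list(ncomp = which.min(rmse), rmse = rmse)
}

#' Tune random-forest hyperparameters by inner cross-validation
#'
#' Grid search over `num.trees` and `mtry` scored by inner-CV RMSE on
#' the training rows, as done per outer resampling step.
#'
#' @param features Training rows of a preprocessed feature table.
#' @param ntree_grid Candidate tree counts (bounds 100-1000).
#' @param mtry_grid Candidate `mtry` values (bounded by the number of
#'   features and 11).
#' @param inner `"cv"` (k-fold, default) or `"loo"` (leave-one-out).
#' @param k Inner folds when `inner = "cv"`.
#' @param seed Seed.
#' @return List: `num.trees`, `mtry`, `rmse` (grid results data.frame).
#' @export
tune_rf <- function(features, ntree_grid = c(100, 250, 500, 750, 1000),
                    mtry_grid = NULL, inner = c("cv", "loo"), k = 10,
                    seed = 1) {
  inner <- match.arg(inner)
  fx <- feature_names(features)
  if (is.null(mtry_grid)) mtry_grid <- seq_len(min(11, length(fx)))
  mtry_grid <- mtry_grid[mtry_grid <= length(fx)]
  X <- features[, fx, drop = FALSE]
  y <- features$response
  n <- nrow(X)
  if (n < 20) stop("need at least 20 training rows for tuning")
  set.seed(seed)
  fold_id <- if (inner == "loo") seq_len(n) else rep_len(seq_len(k), n)[sample(n)]
  grid <- expand.grid(num.trees = ntree_grid, mtry = mtry_grid)
  grid$rmse <- NA_real_
  for (gi in seq_len(nrow(grid))) {
    sse <- 0
    for (f in unique(fold_id)) {
      tr <- fold_id != f
      rf <- ranger::ranger(x = X[tr, , drop = FALSE], y = y[tr],
                           num.trees = grid$num.trees[gi],
                           mtry = grid$mtry[gi], seed = seed,
                           num.threads = 1)
      pred <- stats::predict(rf, X[!tr, , drop = FALSE],
                             num.threads = 1)$predictions
      sse <- sse + sum((y[!tr] - pred)^2)
    }
    grid$rmse[gi] <- sqrt(sse / n)
    if (!any(is.finite(grid$rmse[seq_len(gi)]))) next
  }
  if (!any(is.finite(grid$rmse))) stop("tuning grid produced no finite scores")
  best <- grid[which.min(grid$rmse), ]
  list(num.trees = best$num.trees, mtry = best$mtry, rmse = grid)
}

#' Cross-validated phenomic prediction
#'
#' Fits the learner on each training fold (PLS standardizes inside the
#' fold; no leakage) and pools the out-of-fold predictions. Reports
#' RMSE, normalized RMSE (`100 * rmse / mean(observed)`, percent) and
#' Spearman's rank correlation on the pooled predictions. For the
#' `"unseen_GE"` scheme, every fold is additionally asserted to share
#' neither genotype nor year-site with its test cell.
#'
#' @param features Preprocessed feature table.
#' @param learner `"pls"` or `"rf"`.
#' @param scheme A [cv_scheme()].
#' @param ncomp PLS components (fixed per task, see [tune_pls()]).
#' @param num.trees,mtry Random-forest parameters (used when
#'   `tune = FALSE`).
#' @param tune Tune the random forest per outer fold (inner 10-fold CV,
#'   leave-one-out for `"unseen_GE"`).
#' @param feature_set Optional subset of feature columns (e.g. only
#'   timing traits).
#' @param seed Seed for folds and the stochastic learner.
#' @return Object of class `"prediction_report"`: `rmse`, `nrmse`,
#'   `r_s`, `predictions` (observed, predicted, fold), `learner`,
#'   `scheme`.
#' @export
cross_validate <- function(features, learner = c("pls", "rf"), scheme,
                           ncomp = 1, num.trees = 500, mtry = NULL,
                           tune = FALSE, feature_set = NULL, seed = 1) {
  learner <- match.arg(learner)
  fx <- feature_names(features)
  if (!is.null(feature_set)) fx <- intersect(fx, feature_set)
  stopifnot(length(fx) >= 1)
  X <- as.matrix(features[, fx, drop = FALSE])
  y <- features$response
  folds <- make_folds(features, scheme, seed = seed)
  pred <- rep(NA_real_, nrow(X))
  predf <- data.frame()
  for (fi in seq_along(folds)) {
    fold <- folds[[fi]]
    if (length(fold$train) == 0) stop("fold ", fi, " has an empty training set")
    if (scheme$kind == "unseen_GE") {
      stopifnot(
        !any(features$genotype[fold$train] %in% features$genotype[fold$test]),
        !any(features$year_site[fold$train] %in% features$year_site[fold$test]))
    }
    if (learner == "pls") {
      fit <- pls_fit(X[fold$train, , drop = FALSE], y[fold$train], ncomp)
      p_te <- predict(fit, X[fold$test, , drop = FALSE])
    } else {
      pars <- list(num.trees = num.trees,
                   mtry = if (is.null(mtry)) max(1, floor(length(fx) / 3)) else mtry)
      if (tune) {
        tr_tab <- features[fold$train, c(fx, "response")]
        tuned <- tune_rf(tr_tab,
                         inner = if (scheme$kind == "unseen_GE") "loo" else "cv",
                         seed = seed)
        pars <- tuned[c("num.trees", "mtry")]
      }
      rf <- ranger::ranger(x = X[fold$train, , drop = FALSE], y = y[fold$train],
                           num.trees = pars$num.trees, mtry = pars$mtry,
                           seed = seed + fi, num.threads = 1)
      p_te <- stats::predict(rf, X[fold$test, , drop = FALSE],
                             num.threads = 1)$predictions
    }
    predf <- rbind(predf, data.frame(row = fold$test, observed = y[fold$test],
                                     predicted = as.numeric(p_te), fold = fi))
  }
  out <- list(learner = learner, scheme = scheme$kind,
              n_folds = length(folds), features = fx,
              predictions = predf)
  out$rmse <- sqrt(mean((predf$observed - predf$predicted)^2))
  out$nrmse <- 100 * out$rmse / mean(predf$observed)
  out$r_s <- stats::cor(predf$observed, predf$predicted, method = "spearman")
  class(out) <- "prediction_report"
  out
}

#' @export
print.prediction_report <- function(x, ...) {
  cat(sprintf("%s / %s: r_s = %.2f, RMSE = %.3f, nRMSE = %.1f%% (%d folds)\n",
              toupper(x$learner), x$scheme, x$r_s, x$rmse, x$nrmse, x$n_folds))
  invisible(x)
}

#' Feature importance with uncertainty
#'
#' PLS: the signed coefficients on standardized predictors (the score
#' summarizing all components per feature), with 95% intervals from
#' jackknife (leave-one-out) variance estimates. Random forest: mean
#' increase in out-of-bag mean-squared error over `n_perm` permutation
#' runs per feature, with 95% intervals from the runs.
#'
#' @param features Preprocessed feature table.
#' @param learner `"pls"` or `"rf"`.
#' @param ncomp PLS components.
#' @param num.trees,mtry Random-forest parameters.
#' @param n_perm Permutation runs per feature for the forest (default 50).
#' @param seed Seed.
#' @return data.frame: `feature`, `score`, `lo95`, `hi95`.
#' @export
feature_importance <- function(features, learner = c("pls", "rf"),
                               ncomp = 1, num.trees = 500, mtry = NULL,
                               n_perm = 50, seed = 1) {
  learner <- match.arg(learner)
  fx <- feature_names(features)
  X <- as.matrix(features[, fx, drop = FALSE])
  y <- features$response
  n <- nrow(X)
  if (learner == "pls") {
    full <- pls_fit(X, y, ncomp)$coef_std
    jk <- t(vapply(seq_len(n), function(i) {
      pls_fit(X[-i, , drop = FALSE], y[-i], ncomp)$coef_std
    }, numeric(length(fx))))
    jm <- colMeans(jk)
    se <- sqrt((n - 1) / n * colSums(sweep(jk, 2, jm)^2))
    return(data.frame(feature = fx, score = as.numeric(full),
                      lo95 = as.numeric(full - 1.96 * se),
                      hi95 = as.numeric(full + 1.96 * se),
                      row.names = NULL, stringsAsFactors = FALSE))
  }
  if (is.null(mtry)) mtry <- max(1, floor(length(fx) / 3))
  rf <- ranger::ranger(x = X, y = y, num.trees = num.trees, mtry = mtry,
                       keep.inbag = TRUE, seed = seed, num.threads = 1)
  inbag <- do.call(cbind, rf$inbag.counts)
  oob <- inbag == 0
  if (any(rowSums(oob) == 0)) stop("some rows are never out of bag; increase num.trees")
  oob_pred_from <- function(Xp) {
    all_p <- stats::predict(rf, Xp, predict.all = TRUE,
                            num.threads = 1)$predictions
    rowSums(all_p * oob) / rowSums(oob)
  }
  base_mse <- mean((y - oob_pred_from(X))^2)
  set.seed(seed)
  out <- lapply(fx, function(f) {
    incr <- vapply(seq_len(n_perm), function(r) {
      Xp <- X
      Xp[, f] <- sample(Xp[, f])
      mean((y - oob_pred_from(Xp))^2) - base_mse
    }, 0)
    data.frame(feature = f, score = mean(incr),
               lo95 = as.numeric(stats::quantile(incr, 0.025)),
               hi95 = as.numeric(stats::quantile(incr, 0.975)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
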