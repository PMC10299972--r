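mk_features <- function(n = 60, seed = 1, p = 4) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  data.frame(genotype = sprintf("g%02d", rep(seq_len(n / 2), 2)),
             year_site = rep(c("A", "B"), each = n / 2), X,
             response = drop(X %*% c(1, -1, 0.5, 0)) + rnorm(n, 0, 0.1))
}

test_that("preprocessing applies the filtering rules at their boundaries", {
  d <- data.frame(genotype = sprintf("g%d", 1:4),
                  n_tiller = c(7999, 8000, 8001, 500),
                  r_max = c(1, 2, 3, 4), T_min = c(1, 2, 3, 4),
                  lrc = c(1, 2, 3, 4), response = 1:4)
  out <- preprocess_features(d, "yield")
  expect_setequal(out$genotype, c("g1", "g2", "g4")) # 8001 removed, 8000 kept
  # other tasks keep high tiller counts
  expect_identical(nrow(preprocess_features(d, "protein")), 4L)
})

test_that("rows with failed dose-response fits are removed", {
  # 2200 rows of which 354 have missing C traits -> 1846 retained
  set.seed(2)
  n <- 2200
  d <- data.frame(genotype = sprintf("g%04d", 1:n),
                  r_max = rnorm(n), T_min = rnorm(n), lrc = rnorm(n),
                  PH_max = rnorm(n), response = rnorm(n))
  miss <- sample(n, 354)
  d$r_max[miss[1:118]] <- NA
  d$T_min[miss[119:236]] <- NA
  d$lrc[miss[237:354]] <- NA
  expect_identical(nrow(preprocess_features(d, "decision")), 1846L)
})

test_that("decision labels map to the ordinal selection scale", {
  expect_identical(
    decision_to_ordinal(c("selected", "sister_selected", "repeated",
                          "sister_repeated", "discarded")),
    c(3, 2, 1, 0, -1))
  expect_error(decision_to_ordinal("maybe"), "unknown")
  d <- data.frame(genotype = "g1", r_max = 1, T_min = 1, lrc = 1,
                  response = "discarded", stringsAsFactors = FALSE)
  expect_identical(preprocess_features(d, "decision")$response, -1)
})

test_that("the study-mirroring design yields 5 / 45 / 179 folds", {
  meta <- study_meta()
  expect_identical(nrow(meta), 179L)
  expect_length(make_folds(meta, cv_scheme("unseen_E")), 5L)
  expect_length(make_folds(meta, cv_scheme("unseen_G")), 45L)
  folds <- make_folds(meta, cv_scheme("unseen_GE"))
  expect_length(folds, 179L)
  # leakage guard: training sets share neither genotype nor year-site
  for (f in folds) {
    expect_false(meta$genotype[f$test] %in% meta$genotype[f$train])
    expect_false(meta$year_site[f$test] %in% meta$year_site[f$train])
  }
})

test_that("unseen-genotype folds partition the data", {
  meta <- study_meta()
  folds <- make_folds(meta, cv_scheme("unseen_G"))
  tests <- sort(unlist(lapply(folds, `[[`, "test")))
  expect_identical(tests, seq_len(nrow(meta)))
  for (f in folds) expect_identical(sort(c(f$train, f$test)), seq_len(nrow(meta)))
})

test_that("repeated k-fold produces k x repeats folds covering all rows", {
  meta <- study_meta()
  folds <- make_folds(meta, cv_scheme("kfold", k = 8, repeats = 5), seed = 3)
  expect_length(folds, 40L)
  first_rep <- sort(unlist(lapply(folds[1:8], `[[`, "test")))
  expect_identical(first_rep, seq_len(nrow(meta)))
})

test_that("a perfectly linear response is recovered by PLS", {
  d <- mk_features(seed = 3)
  d$response <- drop(as.matrix(d[, paste0("f", 1:4)]) %*% c(1, -2, 0.5, 0)) + 3
  rep <- cross_validate(d, "pls", cv_scheme("kfold", k = 5, repeats = 1),
                        ncomp = 4)
  expect_gte(rep$r_s, 0.999)
  expect_lte(rep$nrmse, 1)
})

test_that("the nRMSE definition reproduces the printed pair", {
  # RMSE 1.23 t/ha at an observed mean of 5.913 t/ha -> 20.8%
  set.seed(5)
  n <- 2000
  obs <- rnorm(n, 0, 0.3)
  obs <- obs - mean(obs) + 5.913
  pred <- obs + rnorm(n)
  pred <- obs + (pred - obs) / sqrt(mean((pred - obs)^2)) * 1.23
  rmse <- sqrt(mean((obs - pred)^2))
  expect_equal(rmse, 1.23, tolerance = 1e-10)
  expect_equal(100 * rmse / mean(obs), 20.80, tolerance = 0.005)
})

test_that("nRMSE and rank correlation are scale invariant", {
  d <- mk_features(seed = 6)
  r1 <- cross_validate(d, "pls", cv_scheme("kfold", k = 5, repeats = 1),
                       ncomp = 2, seed = 2)
  d2 <- d
  d2$response <- d2$response * 7
  r2 <- cross_validate(d2, "pls", cv_scheme("kfold", k = 5, repeats = 1),
                       ncomp = 2, seed = 2)
  expect_equal(r1$nrmse, r2$nrmse, tolerance = 1e-8)
  expect_equal(r1$r_s, r2$r_s, tolerance = 1e-8)
})

test_that("a response independent of the features is not 'predicted'", {
  rs <- sapply(1:10, function(s) {
    d <- mk_features(seed = 300 + s)
    d$response <- rnorm(nrow(d))
    cross_validate(d, "pls", cv_scheme("kfold", k = 5, repeats = 1),
                   ncomp = 2, seed = s)$r_s
  })
  expect_lt(mean(abs(rs)), 0.2)
})

test_that("PLS agrees with an independent implementation", {
  skip_if_not_installed("mixOmics")
  d <- mk_features(seed = 9)
  X <- as.matrix(d[, paste0("f", 1:4)])
  y <- d$response
  for (nc in 1:3) {
    ours <- pls_fit(X, y, nc)
    ref <- mixOmics::pls(X, y, ncomp = nc, mode = "regression",
                         scale = TRUE)
    pred_ref <- predict(ref, X)$predict[, 1, nc]
    expect_equal(unname(predict(ours, X)), unname(pred_ref),
                 tolerance = 1e-6)
  }
})

test_that("tuning finds a single component for one-factor data", {
  hits <- sapply(1:10, function(s) {
    set.seed(s)
    n <- 100
    lat <- rnorm(n)
    X <- sapply(1:6, function(k) lat + rnorm(n, 0, 0.3))
    colnames(X) <- paste0("f", 1:6)
    d <- data.frame(genotype = sprintf("g%d", 1:n), X,
                    response = lat + rnorm(n, 0, 0.3))
    tune_pls(d, ncomp_max = 5, seed = s)$ncomp
  })
  expect_gte(mean(hits == 1), 0.9)
})

test_that("random-forest tuning respects the mtry bounds", {
  d <- mk_features(n = 60, seed = 10)
  tuned <- tune_rf(d, ntree_grid = c(100, 250), k = 5, seed = 1)
  expect_true(tuned$mtry >= 1 && tuned$mtry <= min(11, 4))
  expect_true(tuned$num.trees %in% c(100, 250))
  expect_error(tune_rf(d[1:10, ], k = 2), "20 training rows")
})

test_that("random forests overfit unseen environments more than unseen genotypes", {
  gaps <- sapply(1:12, function(s) {
    d <- cell_features(s, env_effect = function(v) sin(2 * v) + v^2)
    rfG <- cross_validate(d, "rf", cv_scheme("unseen_G"), num.trees = 200,
                          seed = s)$r_s
    rfE <- cross_validate(d, "rf", cv_scheme("unseen_E"), num.trees = 200,
                          seed = s)$r_s
    rfG - rfE
  })
  expect_gte(mean(gaps), 0.2)
})

test_that("PLS degrades less than RF when the unseen environment extrapolates", {
  gaps <- t(sapply(1:5, function(s) {
    d <- cell_features(s, v = c(-2, -1, 0, 1, 4), env_effect = identity)
    c(rf = cross_validate(d, "rf", cv_scheme("unseen_G"), num.trees = 200,
                          seed = s)$r_s -
        cross_validate(d, "rf", cv_scheme("unseen_E"), num.trees = 200,
                       seed = s)$r_s,
      pls = cross_validate(d, "pls", cv_scheme("unseen_G"), ncomp = 2,
                           seed = s)$r_s -
        cross_validate(d, "pls", cv_scheme("unseen_E"), ncomp = 2,
                       seed = s)$r_s)
  }))
  expect_lt(mean(gaps[, "pls"]), mean(gaps[, "rf"]))
})

test_that("feature importance ranks informative features first", {
  set.seed(20)
  n <- 80
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("f", 1:4)))
  d <- data.frame(genotype = sprintf("g%d", 1:n), X,
                  response = 2 * X[, 1] + rnorm(n, 0, 0.3))
  ip <- feature_importance(d, "pls", ncomp = 2)
  expect_identical(ip$feature[which.max(abs(ip$score))], "f1")
  ir <- feature_importance(d, "rf", num.trees = 200, n_perm = 20, seed = 1)
  expect_identical(ir$feature[which.max(ir$score)], "f1")
  # null features: permutation interval covers zero
  null_rows <- ir[ir$feature != "f1", ]
  expect_true(all(null_rows$lo95 <= 0.05))
})

test_that("duplicated strong features share their PLS score", {
  set.seed(21)
  n <- 100
  f1 <- rnorm(n)
  X <- cbind(f1 = f1, f1b = f1 + rnorm(n, 0, 1e-3), f2 = rnorm(n))
  d <- data.frame(genotype = sprintf("g%d", 1:n), X,
                  response = f1 + rnorm(n, 0, 0.2))
  ip <- feature_importance(d, "pls", ncomp = 1)
  s <- setNames(ip$score, ip$feature)
  expect_equal(unname(s["f1"]), unname(s["f1b"]), tolerance = 0.05)
})
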