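test_that("fold assignment is balanced, reproducible, and guarded", {
  expect_error(assign_folds(10, 1), "K >= 2")
  expect_error(assign_folds(5, 6), "exceed")
  f <- assign_folds(10, 10, seed = 1)
  expect_equal(sort(f), 1:10)  # singleton folds
  f2 <- assign_folds(103, 10, seed = 2)
  expect_true(all(table(f2) %in% c(10, 11)))  # pigeonhole
  expect_identical(assign_folds(103, 10, seed = 2), f2)
})

test_that("monthly layers reduce to sign-fixed principal components", {
  g <- tiny_grid(5, years = 2005)
  nc <- 25
  # toy: 12 monthly layers on 25 pixels, 1 year
  set.seed(12)
  base <- rnorm(nc)
  monthly <- array(NA_real_, c(nc, 1, 12, 1))
  for (m in 1:12) monthly[, 1, m, 1] <- base * sin(2 * pi * m / 12) +
      0.3 * rnorm(nc)
  st <- resistmap:::new_covariate_stack(
    g, 2005, array(rnorm(nc), c(nc, 1, 1)), "cov01_lag0",
    monthly = monthly, monthly_names = "mcov01")
  out <- monthly_to_pcs(st)
  expect_equal(dim(out$layers)[3], 4)  # 1 yearly + 3 PCs
  ev <- attr(out, "pc_explained")
  expect_true(all(diff(as.vector(ev[1, ])) <= 0))  # non-increasing
  # oracle: scores from an independent eigendecomposition of the covariance
  M <- matrix(monthly[, 1, , 1], nc, 12)
  Mc <- scale(M, center = TRUE, scale = FALSE)
  eig <- eigen(cov(M), symmetric = TRUE)
  for (k in 1:3) {
    v <- eig$vectors[, k]
    if (v[which.max(abs(v))] < 0) v <- -v
    expect_equal(out$layers[, 1, 1 + k], as.vector(Mc %*% v),
                 tolerance = 1e-8)
  }
  # degenerate: identical months -> PC1 explains everything
  for (m in 1:12) monthly[, 1, m, 1] <- base
  st$monthly <- monthly
  out2 <- monthly_to_pcs(st)
  ev2 <- attr(out2, "pc_explained")
  expect_equal(ev2[1, 1], 1)
  expect_equal(sd(out2$layers[, 1, 3]), 0)  # PC2 scores have no variance
  # fewer than 12 layers rejected
  st$monthly <- monthly[, , 1:11, , drop = FALSE]
  expect_error(monthly_to_pcs(st), "12 monthly layers")
})

test_that("feature assembly is complete with a stable column order", {
  cfg <- small_sim_config(seed = 14)
  dat <- simulate_dataset(cfg)
  stack <- monthly_to_pcs(dat$stack)
  obs <- combine_labels(dat$bioassay, dat$allele, cfg$grid)
  X <- assemble_features(obs, stack)
  expect_false(anyNA(X))
  expect_equal(ncol(X), dim(stack$layers)[3] +
                 length(unique(obs$group)) + 1)
  expect_equal(colnames(X)[ncol(X)], "year")
  # group one-hot: exactly one indicator per row
  gcols <- grep("^group\\.", colnames(X))
  expect_true(all(rowSums(X[, gcols]) == 1))
  # prediction-time assembly reuses the recorded group levels
  X1 <- assemble_features(obs[1, ], stack, attr(X, "group_levels"))
  expect_identical(colnames(X1), colnames(X))
})

test_that("out-of-fold predictions are leakage-free cross means", {
  # constant features make every learner predict its training-label mean,
  # so with K = 2 and a 0/1 fold-indicator label the out-of-fold entry of
  # every row must equal the mean of the OTHER fold: a hand-computable
  # oracle that any in-fold leakage would break.
  n <- 40
  X <- matrix(1, n, 2)
  folds <- rep(1:2, each = 20)
  y <- as.numeric(folds == 1)   # fold 1 labels are 1, fold 2 labels are 0
  M <- oof_predict(list(gbt = list(nrounds = 10, max_depth = 2,
                                   subsample = 1),
                        rf = list(ntree = 10),
                        bgam = list(mstop = 10)),
                   X, y, folds, seed = 3)
  expect_equal(dim(M), c(40, 3))
  for (p in 1:3) {
    expect_equal(unname(M[folds == 1, p]), rep(0, 20), tolerance = 1e-8)
    expect_equal(unname(M[folds == 2, p]), rep(1, 20), tolerance = 1e-8)
  }
  expect_error(oof_predict(list(rf = list(ntree = 5)), X, y, rep(1, n)),
               "zero training rows")
})

test_that("random-forest out-of-fold error exceeds in-sample error", {
  worse <- 0
  for (r in 1:20) {
    set.seed(400 + r)
    n <- 120
    X <- matrix(rnorm(n * 3), n, 3)
    y <- sin(X[, 1]) + rnorm(n, 0, 0.3)
    folds <- assign_folds(n, 4, seed = r)
    M <- oof_predict(list(rf = list(ntree = 25)), X, y, folds, seed = r)
    fit <- fit_rf(X, y, ntree = 25, seed = r)
    oof_rmse <- sqrt(mean((M[, 1] - y)^2))
    ins_rmse <- sqrt(mean((predict(fit, X) - y)^2))
    worse <- worse + (oof_rmse >= ins_rmse)
  }
  expect_gte(worse, 18)
})

test_that("tuning selects by CV RMSE and is reproducible", {
  set.seed(16)
  n <- 150
  X <- matrix(rnorm(n * 3), n, 3)
  y <- X[, 1] + rnorm(n, 0, 0.2)
  expect_error(fit_level0(X, y, "gbt", tuning_grid = list()), "empty")
  f1 <- fit_level0(X, y, "gbt",
                   tuning_grid = list(list(nrounds = 10, max_depth = 1),
                                      list(nrounds = 40, max_depth = 2)),
                   K = 3, seed = 4)
  f2 <- fit_level0(X, y, "gbt",
                   tuning_grid = list(list(nrounds = 10, max_depth = 1),
                                      list(nrounds = 40, max_depth = 2)),
                   K = 3, seed = 4)
  expect_identical(f1$tuning_report, f2$tuning_report)
  expect_equal(sum(f1$tuning_report$chosen), 1)
  expect_equal(which(f1$tuning_report$chosen),
               which.min(f1$tuning_report$cv_rmse))
})

test_that("the fitted ensemble keeps coherent bookkeeping", {
  cfg <- small_sim_config(seed = 17, n_obs = 120, n_vgsc = 15)
  dat <- simulate_dataset(cfg)
  stack <- monthly_to_pcs(dat$stack)
  obs <- combine_labels(dat$bioassay, dat$allele, cfg$grid)
  X <- assemble_features(obs, stack)
  ens <- fit_ensemble(X, obs$label, specs = fast_specs, K = 5, seed = 18)
  expect_s3_class(ens, "level0_ensemble")
  expect_equal(dim(ens$oof_matrix), c(nrow(X), 3))
  expect_false(anyNA(ens$oof_matrix))
  expect_equal(length(ens$fold_assignment), nrow(X))
  expect_equal(colSums(ens$importances), c(gbt = 1, rf = 1, bgam = 1),
               tolerance = 1e-9)
  # every learner's oof predictions correlate positively with the label
  for (p in 1:3) expect_gt(cor(ens$oof_matrix[, p], obs$label), 0)
})
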