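# The three constituent machine-learning paradigms used as level-0 models:
#   * gradient-boosted regression trees with DART-style tree dropout,
#   * bagged regression trees with random feature subsetting (random forest),
#   * componentwise boosting of smooth univariate base learners (BGAM).
# The regression-tree core is compiled (src/tree.cpp); each fit derives a
# deterministic integer stream from its `seed` argument so results do not
# depend on R's global RNG state except through explicit seeds.

derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 16807) %% 2147483647)
}

#' Gradient-boosted trees with DART-style dropout
#'
#' Squared-error gradient boosting of shallow regression trees. At each
#' iteration a random subset of the existing trees is dropped (each with
#' probability `drop_rate`; when none is dropped one is forced if available),
#' the new tree is fitted to the residual of the retained ensemble, scaled by
#' `1/(k+1)` where `k` is the number of dropped trees, and the dropped trees
#' are scaled back by `k/(k+1)` - the standard dropout regularisation for
#' boosted ensembles. `drop_rate = 0` gives plain gradient boosting.
#'
#' @param X Numeric feature matrix.
#' @param y Numeric label vector (transformed scale).
#' @param nrounds Number of boosting iterations.
#' @param max_depth Tree depth.
#' @param eta Learning rate.
#' @param drop_rate Per-tree dropout probability.
#' @param min_node Minimum rows per leaf.
#' @param subsample Row subsampling fraction per iteration.
#' @param seed Integer seed.
#' @return Object of class `gbt_model`.
#' @export
fit_gbt <- function(X, y, nrounds = 80, max_depth = 3, eta = 0.1,
                    drop_rate = 0.05, min_node = 5, subsample = 0.8,
                    seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(length(y) == n, all(is.finite(y)))
  set.seed(derive_seed(seed, 0))
  base <- mean(y)
  trees <- vector("list", nrounds)
  wts <- numeric(nrounds)
  gain <- numeric(ncol(X))
  pred <- rep(base, n)   # current full-ensemble prediction
  tree_pred <- matrix(0, n, nrounds)
  for (m in seq_len(nrounds)) {
    prev <- seq_len(m - 1L)
    drop <- prev[runif(length(prev)) < drop_rate]
    if (length(prev) && !length(drop)) drop <- sample(prev, 1)
    k <- length(drop)
    pred_keep <- pred
    if (k) pred_keep <- pred - tree_pred[, drop, drop = FALSE] %*% wts[drop]
    r <- y - pred_keep
    rows <- if (subsample < 1) {
      sample.int(n, max(2, floor(subsample * n)))
    } else seq_len(n)
    tr <- grow_tree_cpp(X, r, rows - 1L, max_depth, min_node, ncol(X),
                        derive_seed(seed, m))
    gain <- gain + tr$gain
    tp <- predict_tree_cpp(tr, X)
    w_new <- eta / (k + 1)
    if (k) {
      scale <- k / (k + 1)
      pred <- pred - (1 - scale) * as.vector(
        tree_pred[, drop, drop = FALSE] %*% wts[drop])
      wts[drop] <- wts[drop] * scale
    }
    trees[[m]] <- tr
    wts[m] <- w_new
    tree_pred[, m] <- tp
    pred <- pred + w_new * tp
  }
  structure(list(trees = trees, weights = wts, base = base, gain = gain,
                 feature_names = colnames(X),
                 params = list(nrounds = nrounds, max_depth = max_depth,
                               eta = eta, drop_rate = drop_rate,
                               min_node = min_node, subsample = subsample)),
            class = "gbt_model")
}

#' @export
predict.gbt_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  object$base + as.vector(predict_ensemble_cpp(object$trees,
                                               object$weights, X))
}

#' Bagged regression trees with random feature subsetting (random forest)
#'
#' @param X,y Training data.
#' @param ntree Number of trees.
#' @param mtry Features tried per split; default `max(1, floor(p / 3))`.
#' @param min_node Minimum rows per leaf.
#' @param max_depth Depth cap (large default: near-full trees).
#' @param seed Integer seed.
#' @return Object of class `rf_model` carrying out-of-bag bookkeeping for
#'   permutation importance.
#' @export
fit_rf <- function(X, y, ntree = 100, mtry = NULL, min_node = 5,
                   max_depth = 25, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(length(y) == n, all(is.finite(y)))
  if (is.null(mtry)) mtry <- max(1L, floor(ncol(X) / 3))
  set.seed(derive_seed(seed, 0))
  trees <- vector("list", ntree)
  inbag <- matrix(FALSE, n, ntree)
  for (b in seq_len(ntree)) {
    rows <- sample.int(n, n, replace = TRUE)
    inbag[unique(rows), b] <- TRUE
    trees[[b]] <- grow_tree_cpp(X, y, rows - 1L, max_depth, min_node, mtry,
                                derive_seed(seed, b))
  }
  structure(list(trees = trees, inbag = inbag, X = X, y = y, mtry = mtry,
                 feature_names = colnames(X),
                 params = list(ntree = ntree, mtry = mtry,
                               min_node = min_node, max_depth = max_depth),
                 seed = seed),
            class = "rf_model")
}

#' @export
predict.rf_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  ntree <- length(object$trees)
  as.vector(predict_ensemble_cpp(object$trees, rep(1 / ntree, ntree), X))
}

# Univariate base learners for componentwise boosting: a ridge-penalised
# cubic B-spline smoother per continuous feature (effective df ~ `df`), a
# plain linear learner for features with few distinct values (e.g. one-hot
# group indicators). Hat components are precomputed once per feature.
make_base_learner <- function(x, df = 4) {
  ux <- unique(x)
  if (length(ux) < 6) {
    B <- cbind(1, x)
    H <- tryCatch(solve(crossprod(B) + 1e-8 * diag(2), t(B)),
                  error = function(e) NULL)
    return(list(kind = "linear", H = H, predict_basis = function(newx)
      cbind(1, newx)))
  }
  bknots <- range(x)
  knots <- quantile(x, probs = seq(0.1, 0.9, length.out = 4), names = FALSE)
  B <- splines::bs(x, knots = knots, Boundary.knots = bknots, degree = 3,
                   intercept = TRUE)
  BtB <- crossprod(B)
  pen <- diag(ncol(B))
  # calibrate ridge penalty so trace of the smoother matrix ~ df
  edf <- function(lambda)
    sum(diag(solve(BtB + lambda * pen, BtB))) - df
  lambda <- tryCatch(uniroot(edf, c(1e-8, 1e8))$root, error = function(e) 1)
  H <- solve(BtB + lambda * pen, t(B))
  predict_basis <- function(newx) {
    newx <- pmin(pmax(newx, bknots[1]), bknots[2])
    splines::bs(newx, knots = knots, Boundary.knots = bknots, degree = 3,
                intercept = TRUE)
  }
  list(kind = "spline", H = H, B = B, predict_basis = predict_basis)
}

#' Componentwise-boosted additive model (BGAM)
#'
#' Gradient boosting where each iteration fits every feature's univariate
#' smooth base learner to the current residuals and adds a shrunken copy of
#' the best one, yielding a sparse additive model. Variable importance is
#' the cumulative training-error reduction attributed to each selected base
#' learner.
#'
#' @param X,y Training data.
#' @param mstop Number of boosting iterations.
#' @param nu Shrinkage (step length).
#' @param df Target effective degrees of freedom of the spline learners.
#' @param seed Unused (the fit is deterministic) but accepted for interface
#'   symmetry.
#' @return Object of class `bgam_model`.
#' @export
fit_bgam <- function(X, y, mstop = 100, nu = 0.1, df = 4, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  stopifnot(length(y) == n, all(is.finite(y)))
  learners <- vector("list", p)
  usable <- logical(p)
  for (j in seq_len(p)) {
    if (length(unique(X[, j])) < 2) next  # constant feature: skip
    bl <- make_base_learner(X[, j], df)
    if (is.null(bl$H)) next
    learners[[j]] <- bl
    usable[j] <- TRUE
  }
  offset <- mean(y)
  fitted <- rep(offset, n)
  coefs <- lapply(seq_len(p), function(j)
    if (usable[j]) numeric(nrow(learners[[j]]$H)) else NULL)
  reduction <- numeric(p)
  basis_cache <- lapply(seq_len(p), function(j) {
    if (!usable[j]) return(NULL)
    bl <- learners[[j]]
    if (bl$kind == "linear") cbind(1, X[, j]) else bl$B
  })
  for (m in seq_len(mstop)) {
    r <- y - fitted
    sse0 <- sum(r^2)
    best <- -1; best_sse <- Inf; best_coef <- NULL; best_fit <- NULL
    for (j in which(usable)) {
      cf <- learners[[j]]$H %*% r
      fj <- as.vector(basis_cache[[j]] %*% cf)
      sse <- sum((r - fj)^2)
      if (sse < best_sse) {
        best <- j; best_sse <- sse; best_coef <- cf; best_fit <- fj
      }
    }
    if (best < 0) break
    fitted <- fitted + nu * best_fit
    coefs[[best]] <- coefs[[best]] + nu * as.vector(best_coef)
    reduction[best] <- reduction[best] + (sse0 - sum((y - fitted)^2))
  }
  structure(list(learners = learners, usable = usable, coefs = coefs,
                 offset = offset, reduction = reduction,
                 feature_names = colnames(X),
                 params = list(mstop = mstop, nu = nu, df = df)),
            class = "bgam_model")
}

#' @export
predict.bgam_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  out <- rep(object$offset, nrow(X))
  for (j in which(object$usable)) {
    if (all(object$coefs[[j]] == 0)) next
    B <- object$learners[[j]]$predict_basis(X[, j])
    out <- out + as.vector(B %*% object$coefs[[j]])
  }
  out
}

learner_kinds <- c("gbt", "rf", "bgam")

#' Fit one level-0 learner by kind
#'
#' @param kind `"gbt"`, `"rf"` or `"bgam"`.
#' @param X,y Training data.
#' @param params Named list of hyperparameters for the kind's fitter.
#' @param seed Integer seed.
#' @return Fitted model object.
#' @export
fit_learner <- function(kind, X, y, params = list(), seed = 1L) {
  kind <- match.arg(kind, learner_kinds)
  fn <- switch(kind, gbt = fit_gbt, rf = fit_rf, bgam = fit_bgam)
  do.call(fn, c(list(X = X, y = y, seed = seed), params))
}
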