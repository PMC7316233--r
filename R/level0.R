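# Level-0 ensemble: assemble the feature matrix (lagged covariates at the
# observation pixel/year, monthly-covariate principal components, group
# factor, collection year), fit the three learners on the combined label
# (bioassay mortalities + Vgsc frequencies, transformed), and produce
# leakage-free K-fold out-of-fold predictions feeding the meta-model.

#' Reduce monthly covariate layers to three principal components
#'
#' For each covariate available on a monthly time step, a PCA is run over
#' its 12 monthly values across pixels x years, and the first three
#' component score layers are appended to the stack (named `*_pc1..3`).
#' Components are ordered by explained variance with the sign fixed so each
#' loading vector's largest-magnitude element is positive.
#'
#' @param stack A `covariate_stack` with a `monthly` array.
#' @return The stack with PC layers appended and the monthly array consumed;
#'   attribute `pc_explained` holds per-covariate explained-variance shares.
#' @export
monthly_to_pcs <- function(stack) {
  if (is.null(stack$monthly)) return(stack)
  dm <- dim(stack$monthly)
  if (dm[3] != 12) stop("input error: expected 12 monthly layers, got ", dm[3])
  nc <- dm[1]; ny <- dm[2]; n_m <- dm[4]
  new_layers <- list(); new_names <- character(0)
  explained <- matrix(NA_real_, n_m, 3,
                      dimnames = list(stack$monthly_names,
                                      paste0("pc", 1:3)))
  for (j in seq_len(n_m)) {
    M <- matrix(stack$monthly[, , , j], nc * ny, 12)
    pc <- prcomp(M, center = TRUE, scale. = FALSE)
    tot <- sum(pc$sdev^2)
    for (k in 1:3) {
      v <- pc$rotation[, k]
      s <- pc$x[, k]
      if (v[which.max(abs(v))] < 0) s <- -s
      new_layers[[length(new_layers) + 1L]] <- matrix(s, nc, ny)
      new_names <- c(new_names,
                     sprintf("%s_pc%d", stack$monthly_names[j], k))
      explained[j, k] <- if (tot > 0) pc$sdev[k]^2 / tot else NA_real_
    }
  }
  old <- stack$layers
  aug <- array(NA_real_, dim = c(nc, ny, dim(old)[3] + length(new_layers)))
  aug[, , seq_len(dim(old)[3])] <- old
  for (i in seq_along(new_layers))
    aug[, , dim(old)[3] + i] <- new_layers[[i]]
  out <- new_covariate_stack(stack$grid, stack$years, aug,
                             c(stack$layer_names, new_names))
  attr(out, "pc_explained") <- explained
  out
}

#' Randomly partition observations into K folds
#'
#' @param n_obs Number of observations.
#' @param K Number of folds, `2 <= K <= n_obs`.
#' @param seed Integer seed.
#' @return Integer vector in `1..K`; fold sizes differ by at most 1.
#' @export
assign_folds <- function(n_obs, K, seed = 1L) {
  if (K < 2) stop("cross-validation needs K >= 2")
  if (K > n_obs) stop("K must not exceed the number of observations")
  set.seed(seed)
  sample(rep(seq_len(K), length.out = n_obs))
}

#' Combine bioassay and allele observations into one modelling table
#'
#' Builds the joint label vector (transformed mortalities and transformed
#' allele frequencies), the observation-group factor, and pixel/year indices
#' on the grid.
#'
#' @param bioassay,allele Observation data frames (allele may be `NULL`).
#' @param grid A [grid_definition()].
#' @param c Empirical-logit smoothing constant.
#' @return Data frame with `kind`, `group`, `cell`, `year`, `year_idx`,
#'   `value` (natural scale), `n`, `label` (transformed scale).
#' @export
combine_labels <- function(bioassay, allele = NULL, grid, c = 0.5) {
  mk <- function(df, kind) {
    value <- if (kind == "bioassay") df$mortality else df$frequency
    n <- if (kind == "bioassay") df$n_tested else df$n_alleles
    data.frame(
      kind = kind,
      group = if (kind == "bioassay")
        observation_group("bioassay", df$insecticide, df$protocol)
      else observation_group("allele"),
      insecticide = if (kind == "bioassay") df$insecticide else NA_character_,
      lon = df$lon, lat = df$lat,
      cell = point_to_cell(grid, df$lon, df$lat),
      year = df$year,
      year_idx = match(df$year, grid$years),
      value = value, n = n,
      label = transform_label(value, n, c))
  }
  out <- mk(bioassay, "bioassay")
  if (!is.null(allele) && nrow(allele)) out <- rbind(out, mk(allele, "allele"))
  if (anyNA(out$cell) || anyNA(out$year_idx))
    stop("observations outside the grid or its year span")
  out
}

#' Assemble the level-0 feature matrix
#'
#' Rows are observations; columns are the lagged covariate layers at the
#' observation's pixel/year, the one-hot-encoded observation group, and the
#' collection year. Monthly covariates must have been reduced via
#' [monthly_to_pcs()] beforehand.
#'
#' @param obs Output of [combine_labels()] (needs `cell`, `year_idx`,
#'   `group`, `year`), or any data frame with those columns.
#' @param stack A `covariate_stack`.
#' @param group_levels Fixed ordering of group levels; defaults to the
#'   sorted groups present, and must be reused for prediction matrices.
#' @return Numeric matrix with stable, recorded column order (attribute
#'   `group_levels`).
#' @export
assemble_features <- function(obs, stack, group_levels = NULL) {
  nl <- dim(stack$layers)[3]
  X_cov <- vapply(seq_len(nl), function(k)
    stack$layers[, , k][cbind(obs$cell, obs$year_idx)],
    numeric(nrow(obs)))
  if (nrow(obs) == 1L) X_cov <- matrix(X_cov, nrow = 1L)
  colnames(X_cov) <- stack$layer_names
  if (is.null(group_levels)) group_levels <- sort(unique(obs$group))
  G <- vapply(group_levels, function(g) as.numeric(obs$group == g),
              numeric(nrow(obs)))
  if (nrow(obs) == 1L) G <- matrix(G, nrow = 1L)
  colnames(G) <- paste0("group.", group_levels)
  X <- cbind(X_cov, G, year = obs$year)
  if (anyNA(X)) stop("feature matrix contains missing values")
  attr(X, "group_levels") <- group_levels
  X
}

default_tuning_grid <- function(kind) {
  switch(kind,
         gbt = list(list(nrounds = 60, max_depth = 2, eta = 0.1),
                    list(nrounds = 60, max_depth = 3, eta = 0.1)),
         rf = list(list(ntree = 60, min_node = 5),
                   list(ntree = 60, min_node = 2)),
         bgam = list(list(mstop = 80, nu = 0.1),
                     list(mstop = 160, nu = 0.1)))
}

#' Tune and fit one level-0 learner
#'
#' Selects the hyperparameter combination minimising K-fold out-of-sample
#' RMSE over the supplied grid, then refits on all rows with the chosen
#' hyperparameters.
#'
#' @param X,y Training data (labels on the transformed scale).
#' @param kind Learner kind (`"gbt"`, `"rf"`, `"bgam"`).
#' @param tuning_grid Non-empty list of hyperparameter lists.
#' @param K Number of tuning folds.
#' @param seed Integer seed (folds and fits derive from it).
#' @return List with `model` (fitted on all data) and `tuning_report`
#'   (a data frame of candidate settings and their CV RMSE).
#' @export
fit_level0 <- function(X, y, kind, tuning_grid = default_tuning_grid(kind),
                       K = 5, seed = 1L) {
  if (!length(tuning_grid)) stop("empty tuning grid")
  folds <- assign_folds(length(y), K, derive_seed(seed, 101))
  rmse <- vapply(seq_along(tuning_grid), function(g) {
    pred <- numeric(length(y))
    for (k in seq_len(K)) {
      test <- folds == k
      fit <- fit_learner(kind, X[!test, , drop = FALSE], y[!test],
                         tuning_grid[[g]], seed = derive_seed(seed, g * 100 + k))
      pred[test] <- predict(fit, X[test, , drop = FALSE])
    }
    sqrt(mean((pred - y)^2))
  }, numeric(1))
  best <- which.min(rmse)
  report <- data.frame(
    setting = vapply(tuning_grid, function(p)
      paste(names(p), unlist(p), sep = "=", collapse = ","), character(1)),
    cv_rmse = rmse, chosen = seq_along(tuning_grid) == best)
  model <- fit_learner(kind, X, y, tuning_grid[[best]],
                       seed = derive_seed(seed, 1))
  list(model = model, params = tuning_grid[[best]], tuning_report = report)
}

#' Out-of-fold prediction matrix for an ensemble specification
#'
#' For each fold `k` and each model: fit on all rows not in `k` and predict
#' the rows in `k`, so every entry is a prediction of a withheld
#' observation. This matrix is the meta-model design matrix.
#'
#' @param specs Named list `kind -> params` of learner specifications.
#' @param X,y Training data.
#' @param fold_assignment Integer fold vector from [assign_folds()].
#' @param seed Integer seed.
#' @return `n x length(specs)` matrix with attribute `fold_assignment`.
#' @export
oof_predict <- function(specs, X, y, fold_assignment, seed = 1L) {
  K <- max(fold_assignment)
  n <- length(y)
  M <- matrix(NA_real_, n, length(specs),
              dimnames = list(NULL, names(specs)))
  for (k in seq_len(K)) {
    test <- fold_assignment == k
    if (all(test)) stop("a fold has zero training rows")
    for (p in seq_along(specs)) {
      fit <- fit_learner(names(specs)[p], X[!test, , drop = FALSE],
                         y[!test], specs[[p]],
                         seed = derive_seed(seed, k * 1000 + p))
      M[test, p] <- predict(fit, X[test, , drop = FALSE])
    }
  }
  attr(M, "fold_assignment") <- fold_assignment
  M
}

#' Per-feature variable importance of a fitted learner
#'
#' Gain (summed training-error reduction over splits) for boosted trees,
#' out-of-bag permutation importance for the forest, and cumulative
#' training-error reduction per selected base learner for the boosted
#' additive model. Scores are nonnegative and normalised to sum to 1.
#'
#' @param model Fitted learner.
#' @param seed Seed for the permutation importance of forests.
#' @return Named numeric vector over features summing to 1.
#' @export
variable_importance <- function(model, seed = 1L) {
  raw <- if (inherits(model, "gbt_model")) {
    model$gain
  } else if (inherits(model, "bgam_model")) {
    model$reduction
  } else if (inherits(model, "rf_model")) {
    rf_permutation_importance(model, seed)
  } else stop("state error: not a fitted level-0 model")
  raw <- pmax(raw, 0)
  if (sum(raw) == 0) raw <- rep(1, length(raw))
  out <- raw / sum(raw)
  names(out) <- if (inherits(model, "rf_model")) model$feature_names
                else model$feature_names
  out
}

rf_permutation_importance <- function(model, seed = 1L) {
  set.seed(derive_seed(seed, 7))
  X <- model$X; y <- model$y
  p <- ncol(X)
  imp <- numeric(p)
  n_used <- 0
  for (b in seq_along(model$trees)) {
    oob <- which(!model$inbag[, b])
    if (length(oob) < 2) next
    n_used <- n_used + 1
    tr <- model$trees[[b]]
    base_mse <- mean((predict_tree_cpp(tr, X[oob, , drop = FALSE]) -
                        y[oob])^2)
    for (j in seq_len(p)) {
      Xp <- X[oob, , drop = FALSE]
      Xp[, j] <- Xp[sample.int(length(oob)), j]
      imp[j] <- imp[j] +
        mean((predict_tree_cpp(tr, Xp) - y[oob])^2) - base_mse
    }
  }
  if (n_used > 0) imp <- imp / n_used
  imp
}

#' Fit the full level-0 ensemble
#'
#' Convenience wrapper: optional per-learner tuning, fold assignment,
#' out-of-fold prediction matrix, in-sample refits on all data, and
#' per-model variable importances.
#'
#' @param X,y Feature matrix and transformed labels.
#' @param specs Named list `kind -> params`; `NULL` entries trigger tuning
#'   over [default_tuning_grid()].
#' @param K Folds for the out-of-fold design (and tuning).
#' @param seed Integer seed.
#' @param tune Whether to run grid tuning for `NULL` specs.
#' @return Object of class `level0_ensemble` with `models`, `oof_matrix`,
#'   `insample_matrix`, `importances`, `fold_assignment`, `tuning_reports`.
#' @export
fit_ensemble <- function(X, y, specs = list(gbt = NULL, rf = NULL,
                                            bgam = NULL),
                         K = 10, seed = 1L, tune = TRUE) {
  tuning_reports <- list()
  for (p in names(specs)) {
    if (is.null(specs[[p]])) {
      if (tune) {
        fl <- fit_level0(X, y, p, K = min(K, 5),
                         seed = derive_seed(seed, match(p, names(specs))))
        specs[[p]] <- fl$params
        tuning_reports[[p]] <- fl$tuning_report
      } else {
        specs[[p]] <- default_tuning_grid(p)[[1]]
      }
    }
  }
  folds <- assign_folds(length(y), K, derive_seed(seed, 11))
  M <- oof_predict(specs, X, y, folds, seed = derive_seed(seed, 12))
  models <- lapply(seq_along(specs), function(p)
    fit_learner(names(specs)[p], X, y, specs[[p]],
                seed = derive_seed(seed, 5000 + p)))
  names(models) <- names(specs)
  insample <- vapply(models, function(m) predict(m, X), numeric(nrow(X)))
  if (nrow(X) == 1L) insample <- matrix(insample, nrow = 1L)
  colnames(insample) <- names(specs)
  importances <- vapply(models, variable_importance, numeric(ncol(X)),
                        seed = derive_seed(seed, 13))
  rownames(importances) <- colnames(X)
  structure(list(models = models, specs = specs, oof_matrix = M,
                 insample_matrix = insample, importances = importances,
                 fold_assignment = folds, tuning_reports = tuning_reports),
            class = "level0_ensemble")
}
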