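# Out-of-sample validation of the full stack: K-fold cross-validation in
# which BOTH layers are refitted per fold (the level-0 learners, with their
# own internal out-of-fold machinery on the training portion only, and the
# meta-model), plus credible-interval coverage and PIT diagnostics.

#' Cross-validate the stacked model
#'
#' Splits the combined observation set (bioassay + allele rows) into K
#' random folds. For each fold, the three level-0 learners are refitted on
#' the training rows (with internal out-of-fold predictions for the
#' meta-model design), a meta-model is refitted per insecticide grouping,
#' and withheld rows are predicted. Errors are reported on both the natural
#' (proportional-mortality) and transformed scales.
#'
#' @param bioassay,allele Observation data frames (allele may be `NULL`).
#' @param stack A `covariate_stack` (monthly layers already reduced).
#' @param grid A [grid_definition()].
#' @param K Number of folds (default 10).
#' @param seed Integer seed (independent of any stacking-design seed).
#' @param specs Named list of level-0 hyperparameters (see
#'   [fit_ensemble()]); defaults are the small fast settings.
#' @param meta_groups Named list mapping meta-model names to insecticide
#'   subsets; default one model for the four pyrethroids jointly and one
#'   for DDT.
#' @param K_inner Folds for the within-training out-of-fold design.
#' @param n_draws Posterior draws per meta-model fit.
#' @param c,n_ref Transformation constants.
#' @return Object of class `validation_report`: per meta-group metrics
#'   (stacked and per-constituent RMSE/MAE on both scales), CI coverage at
#'   nominal levels 0.5/0.8/0.95 (with and without measurement noise), PIT
#'   values, and the fold assignment.
#' @export
cross_validate <- function(bioassay, allele = NULL, stack, grid, K = 10,
                           seed = 1L, specs = NULL,
                           meta_groups = list(pyrethroids = PYRETHROIDS,
                                              DDT = "DDT"),
                           K_inner = 5, n_draws = 150, c = 0.5,
                           n_ref = 100) {
  if (K < 2) stop("cross-validation needs K >= 2")
  if (is.null(specs))
    specs <- list(gbt = list(nrounds = 50, max_depth = 3),
                  rf = list(ntree = 50),
                  bgam = list(mstop = 80))
  obs <- combine_labels(bioassay, allele, grid, c)
  X <- assemble_features(obs, stack)
  group_levels <- attr(X, "group_levels")
  n <- nrow(obs)
  folds <- assign_folds(n, K, derive_seed(seed, 500))

  model_names <- names(specs)
  # collected over folds, per meta group
  coll <- lapply(meta_groups, function(g)
    list(obs_nat = c(), obs_tr = c(), pred_nat = c(), pred_tr = c(),
         pit = c(), mu = NULL, sig = c(),
         l0_tr = NULL, undefined_folds = integer(0)))

  for (k in seq_len(K)) {
    test <- folds == k
    Xtr <- X[!test, , drop = FALSE]
    ytr <- obs$label[!test]
    ens <- fit_ensemble(Xtr, ytr, specs = specs, K = K_inner,
                        seed = derive_seed(seed, 900 + k), tune = FALSE)
    M_test <- vapply(ens$models, function(m)
      predict(m, X[test, , drop = FALSE]), numeric(sum(test)))
    if (sum(test) == 1L) M_test <- matrix(M_test, nrow = 1L)
    colnames(M_test) <- model_names

    for (gname in names(meta_groups)) {
      tr_rows <- !test & obs$kind == "bioassay" &
        obs$insecticide %in% meta_groups[[gname]]
      te_rows <- test & obs$kind == "bioassay" &
        obs$insecticide %in% meta_groups[[gname]]
      if (!any(te_rows)) {
        coll[[gname]]$undefined_folds <- c(coll[[gname]]$undefined_folds, k)
        next
      }
      fit <- fit_stack(obs$label[tr_rows],
                       ens$oof_matrix[which(tr_rows[!test]), , drop = FALSE],
                       obs$cell[tr_rows], obs$year_idx[tr_rows], grid,
                       n_draws = n_draws,
                       seed = derive_seed(seed, 700 + k))
      m_te <- M_test[which(te_rows[test]), , drop = FALSE]
      pd <- predictive_density(fit, m_te, obs$cell[te_rows],
                               obs$year_idx[te_rows], obs$label[te_rows])
      pred_nat <- colMeans(inverse_transform(pd$mu_draws, c, n_ref))
      cl <- coll[[gname]]
      cl$obs_nat <- c(cl$obs_nat, obs$value[te_rows])
      cl$obs_tr <- c(cl$obs_tr, obs$label[te_rows])
      cl$pred_nat <- c(cl$pred_nat, pred_nat)
      cl$pred_tr <- c(cl$pred_tr, pd$mean)
      cl$pit <- c(cl$pit, pd$pit)
      cl$mu <- if (is.null(cl$mu)) pd$mu_draws else cbind(cl$mu, pd$mu_draws)
      cl$sigma_by_fold <- c(cl$sigma_by_fold, list(pd$sigma_draws))
      cl$l0_tr <- rbind(cl$l0_tr, m_te)
      coll[[gname]] <- cl
    }
  }

  rmse <- function(a, b) sqrt(mean((a - b)^2))
  mae <- function(a, b) mean(abs(a - b))
  groups_out <- list()
  for (gname in names(meta_groups)) {
    cl <- coll[[gname]]
    if (!length(cl$obs_nat)) {
      groups_out[[gname]] <- list(defined = FALSE,
                                  undefined_folds = cl$undefined_folds)
      next
    }
    l0_rmse_tr <- apply(cl$l0_tr, 2, rmse, b = cl$obs_tr)
    l0_rmse_nat <- apply(inverse_transform(cl$l0_tr, c, n_ref), 2, rmse,
                         b = cl$obs_nat)
    sig_all <- unlist(cl$sigma_by_fold)
    coverage <- ci_coverage_draws(cl$mu, rep(mean(sig_all), ncol(cl$mu)),
                                  cl$obs_tr, include_noise = TRUE)
    coverage_nonoise <- ci_coverage_draws(cl$mu, NULL, cl$obs_tr,
                                          include_noise = FALSE)
    groups_out[[gname]] <- list(
      defined = TRUE, n = length(cl$obs_nat),
      rmse_natural = rmse(cl$pred_nat, cl$obs_nat),
      mae_natural = mae(cl$pred_nat, cl$obs_nat),
      rmse_transformed = rmse(cl$pred_tr, cl$obs_tr),
      mae_transformed = mae(cl$pred_tr, cl$obs_tr),
      l0_rmse_transformed = l0_rmse_tr,
      l0_rmse_natural = l0_rmse_nat,
      coverage = coverage, coverage_no_noise = coverage_nonoise,
      pit = cl$pit, pit_hist = pit_histogram(cl$pit, 10),
      undefined_folds = cl$undefined_folds)
  }
  structure(list(groups = groups_out, K = K, seed = seed,
                 fold_assignment = folds, specs = specs),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("validation_report (K =", x$K, ")\n")
  for (g in names(x$groups)) {
    gr <- x$groups[[g]]
    if (!isTRUE(gr$defined)) {
      cat(sprintf("  %s: undefined (no held-out rows)\n", g)); next
    }
    cat(sprintf(
      "  %s: n=%d RMSE=%.3f MAE=%.3f (natural); RMSE=%.3f (transformed)\n",
      g, gr$n, gr$rmse_natural, gr$mae_natural, gr$rmse_transformed))
    cat(sprintf("    constituents (transformed RMSE): %s\n",
                paste(sprintf("%s=%.3f", names(gr$l0_rmse_transformed),
                              gr$l0_rmse_transformed), collapse = ", ")))
    cat(sprintf("    95%% coverage (with noise): %.3f\n",
                gr$coverage[["0.95"]]))
  }
  invisible(x)
}

# Shared implementation for ci_coverage: mu D x n draws, optional per-draw
# noise SDs.
ci_coverage_draws <- function(mu, sd_draws, y, include_noise,
                              levels = c(0.5, 0.8, 0.95)) {
  n <- ncol(mu)
  out <- setNames(numeric(length(levels)), as.character(levels))
  for (li in seq_along(levels)) {
    a <- (1 - levels[li]) / 2
    inside <- vapply(seq_len(n), function(i) {
      s <- if (include_noise) sd_draws else rep(0, nrow(mu))
      lo <- mixture_quantile(mu[, i], s, a)
      hi <- mixture_quantile(mu[, i], s, 1 - a)
      y[i] >= lo && y[i] <= hi
    }, logical(1))
    out[li] <- mean(inside)
  }
  out
}

#' Credible-interval coverage of held-out observations
#'
#' Fraction of held-out observations falling inside the central predictive
#' interval at each nominal level. With `include_noise = TRUE` the intervals
#' include the fitted measurement-error variance (the predictive
#' distribution of a replicate bioassay); without it they cover only the
#' latent mean and are strictly narrower.
#'
#' @param pd A `predictive_density` (from [predictive_density()] on
#'   held-out rows).
#' @param include_noise Whether intervals include the noise SD.
#' @param levels Nominal central-interval levels.
#' @return Named numeric vector of coverage proportions.
#' @export
ci_coverage <- function(pd, include_noise = TRUE,
                        levels = c(0.5, 0.8, 0.95)) {
  stopifnot(inherits(pd, "predictive_density"))
  ci_coverage_draws(pd$mu_draws,
                    if (include_noise) pd$sigma_draws else NULL,
                    pd$y, include_noise, levels)
}

#' PIT histogram and uniformity statistic
#'
#' Histogram bin counts of probability-integral-transform values and the
#' Kolmogorov-Smirnov distance from the uniform distribution. A calibrated
#' predictive distribution yields uniform PIT values (a flat histogram).
#'
#' @param pit PIT values in `[0, 1]`.
#' @param n_bins Number of equal-width bins.
#' @return List with `counts`, `breaks`, `ks` (sup-distance from U(0,1)),
#'   `n`.
#' @export
pit_histogram <- function(pit, n_bins = 10) {
  if (!length(pit)) stop("empty PIT input")
  stopifnot(all(pit >= 0 & pit <= 1))
  breaks <- seq(0, 1, length.out = n_bins + 1)
  counts <- as.vector(table(cut(pit, breaks, include.lowest = TRUE)))
  u <- sort(pit)
  n <- length(u)
  ks <- max(pmax(seq_len(n) / n - u, u - (seq_len(n) - 1) / n))
  list(counts = counts, breaks = breaks, ks = ks, n = n)
}
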