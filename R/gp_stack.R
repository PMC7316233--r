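# Level-1 Bayesian Gaussian-process meta-model:
#   g(s_i, t) = w' M_i + f(s_i, t) + e_i,   e_i ~ N(0, sigma^2),
# with nonnegative weights w on the out-of-fold level-0 predictions M, and f
# a separable Matern-type x AR(1) GMRF on the prediction grid. Conditional
# on the four hyperparameters (field sd, spatial range, temporal rho, noise
# sigma) the model is linear-Gaussian and all conditionals are computed
# exactly with sparse algebra (Woodbury identities on the GMRF precision).
# Hyperparameter uncertainty is handled by a Laplace approximation on
# theta = (log sd, log range, atanh rho, log sigma): posterior draws sample
# theta from a heavy-tailed t centred at the Laplace mode, then w from its
# exact truncated-normal conditional and f from its exact GMRF conditional.

theta_pack <- function(sd, range_cells, rho, sigma)
  c(log(sd), log(range_cells), atanh(rho), log(sigma))

theta_unpack <- function(theta)
  list(sd = exp(theta[1]), range_cells = exp(theta[2]),
       rho = tanh(theta[3]), sigma = exp(theta[4]))

ldet_chol <- function(ch) {
  # log-determinant of the matrix factored by a sparse Cholesky
  as.numeric(2 * Matrix::determinant(ch, sqrt = TRUE)$modulus)
}

# Exact nonnegative GLS by KKT subset enumeration (p is small).
nnls_solve <- function(B, b) {
  p <- length(b)
  w <- tryCatch(solve(B, b), error = function(e) rep(NA_real_, p))
  if (!anyNA(w) && all(w >= 0)) return(as.vector(w))
  best <- rep(0, p)
  for (mask in seq_len(2^p) - 1L) {
    S <- which(bitwAnd(mask, 2^(seq_len(p) - 1)) > 0)
    w <- rep(0, p)
    if (length(S)) {
      ws <- tryCatch(solve(B[S, S, drop = FALSE], b[S]),
                     error = function(e) NULL)
      if (is.null(ws) || any(ws < 0)) next
      w[S] <- ws
    }
    grad <- as.vector(B %*% w - b)
    if (all(grad[setdiff(seq_len(p), S)] >= -1e-10)) return(w)
    best <- w
  }
  best
}

# One draw from N(mean, cov) truncated to the nonnegative orthant:
# rejection sampling with a Gibbs fallback.
rtruncnorm_nonneg <- function(mean, cov, prec, start, n_gibbs = 10) {
  p <- length(mean)
  L <- tryCatch(chol(cov), error = function(e) NULL)
  if (!is.null(L)) {
    for (i in 1:50) {
      w <- mean + as.vector(crossprod(L, rnorm(p)))
      if (all(w >= 0)) return(w)
    }
  }
  w <- pmax(start, 1e-8)
  for (s in seq_len(n_gibbs)) {
    for (j in seq_len(p)) {
      cm <- mean[j] - sum(prec[j, -j] * (w[-j] - mean[-j])) / prec[j, j]
      cs <- sqrt(1 / prec[j, j])
      lo <- pnorm(0, cm, cs)
      u <- runif(1, lo, 1)
      w[j] <- qnorm(pmin(u, 1 - 1e-12), cm, cs)
      if (!is.finite(w[j]) || w[j] < 0) w[j] <- 0
    }
  }
  w
}

default_stack_priors <- function(grid) {
  list(sd_scale = 2,          # half-normal scale on the field marginal SD
       sigma_scale = 2,       # half-normal scale on the noise SD
       range_lambda = max(3, sqrt(grid$n_rows * grid$n_cols) / 4))
       # PC-style prior on spatial range (cells): pi(r) ~ r^-2 exp(-lambda/r)
}

log_prior_theta <- function(theta, priors) {
  pr <- theta_unpack(theta)
  lp <- -0.5 * pr$sd^2 / priors$sd_scale^2 + log(pr$sd) +
    -0.5 * pr$sigma^2 / priors$sigma_scale^2 + log(pr$sigma) +
    (-2 * log(pr$range_cells) - priors$range_lambda / pr$range_cells +
       log(pr$range_cells)) +
    log(1 - pr$rho^2)  # uniform(-1,1) on rho, atanh Jacobian
  lp
}

# Per-theta sufficient quantities shared by the likelihood and conditionals.
# `cache` is an environment holding A'A and the symbolic Cholesky pattern of
# P (identical across theta), plus closed-form Kronecker log-determinants of
# the prior precision, so each evaluation costs one numeric factorisation.
stack_workspace <- function(theta, A, M, gv, grid, n_years, cache = NULL) {
  pr <- theta_unpack(theta)
  nlat <- ncol(A)
  ncell <- nlat / n_years
  Qs <- spatial_precision(grid$n_rows, grid$n_cols, pr$range_cells)
  Qt <- ar1_precision(n_years, pr$rho)
  ldetQ <- ncell * (-(n_years - 1) * log(1 - pr$rho^2)) +
    n_years * attr(Qs, "ldet") - 2 * nlat * log(pr$sd)
  Q <- Matrix::forceSymmetric(Matrix::kronecker(Qt, Qs) / pr$sd^2)
  s2 <- pr$sigma^2
  AtA <- if (!is.null(cache)) cache$AtA else Matrix::crossprod(A)
  P <- Matrix::forceSymmetric(Q + AtA / s2)
  chP <- if (!is.null(cache) && !is.null(cache$sym)) {
    Matrix::update(cache$sym, P)
  } else Matrix::Cholesky(P, LDL = FALSE, perm = TRUE)
  if (!is.null(cache) && is.null(cache$sym)) cache$sym <- chP
  sigma_inv <- function(x) {
    x <- as.matrix(x)
    x / s2 - (A %*% Matrix::solve(chP, Matrix::crossprod(A, x))) / s2^2
  }
  SiM <- as.matrix(sigma_inv(M))
  Sig <- as.matrix(sigma_inv(gv))
  B <- crossprod(M, SiM)
  B <- (B + t(B)) / 2
  b <- as.vector(crossprod(M, Sig))
  list(pr = pr, Q = Q, P = P, chP = chP, s2 = s2,
       sigma_inv = sigma_inv, B = B, b = b,
       gSg = sum(gv * Sig),
       ldet_sigma = ldet_chol(chP) - ldetQ + length(gv) * log(s2))
}

neg_log_marginal <- function(theta, A, M, gv, grid, n_years, priors,
                             cache = NULL) {
  if (any(abs(theta) > 30)) return(1e10)
  ws <- tryCatch(stack_workspace(theta, A, M, gv, grid, n_years, cache),
                 error = function(e) NULL)
  if (is.null(ws)) return(1e10)
  Breg <- ws$B + diag(1e-10, ncol(ws$B))
  w_u <- tryCatch(solve(Breg, ws$b), error = function(e) NULL)
  if (is.null(w_u)) return(1e10)
  quad <- ws$gSg - sum(ws$b * w_u)
  ldB <- determinant(Breg, logarithm = TRUE)$modulus
  nll <- 0.5 * (ws$ldet_sigma + quad + as.numeric(ldB)) -
    log_prior_theta(theta, priors)
  if (!is.finite(nll)) 1e10 else nll
}

#' Fit the Gaussian-process stacking meta-model
#'
#' Regresses transformed observations on the out-of-fold level-0 prediction
#' matrix with nonnegative weights (no intercept), a separable
#' spatiotemporal GMRF, and i.i.d. Gaussian noise, returning posterior draws
#' of the weights, the field hyperparameters, the noise SD, and the latent
#' field at every grid pixel x year.
#'
#' @param labels Transformed observation vector `g`.
#' @param oof_matrix `n x p` out-of-fold level-0 prediction matrix `M`
#'   (`p >= 2` models, or 1 for degenerate test cases).
#' @param cell,year_idx Observation pixel indices (row-major) and year
#'   indices on `grid`.
#' @param grid A [grid_definition()].
#' @param priors Optional list overriding [default_stack_priors()].
#' @param n_draws Number of posterior draws (default 200).
#' @param seed Integer seed.
#' @param theta_tail_df Degrees of freedom of the multivariate t used to
#'   sample hyperparameters around the Laplace mode (heavier tails than the
#'   Gaussian guard against approximation optimism).
#' @param fixed_hyperparameters Optional list `(field_sd, range_cells, rho,
#'   sigma)`; when supplied no hyperparameter estimation is performed and
#'   the posterior is the exact linear-Gaussian conditional (used for
#'   oracle-equivalence checks and test doubles).
#' @return Object of class `stack_posterior`.
#' @export
fit_stack <- function(labels, oof_matrix, cell, year_idx, grid,
                      priors = NULL, n_draws = 200, seed = 1L,
                      theta_tail_df = 4,
                      fixed_hyperparameters = NULL) {
  g <- as.numeric(labels)
  M <- as.matrix(oof_matrix)
  n <- length(g)
  stopifnot(nrow(M) == n, length(cell) == n, length(year_idx) == n)
  if (is.null(colnames(M))) colnames(M) <- paste0("model", seq_len(ncol(M)))
  n_years <- length(grid$years)
  nlat <- n_cells(grid) * n_years
  A <- Matrix::sparseMatrix(i = seq_len(n),
                            j = (year_idx - 1L) * n_cells(grid) + cell,
                            x = 1, dims = c(n, nlat))
  priors <- utils::modifyList(default_stack_priors(grid),
                              if (is.null(priors)) list() else priors)
  if (ncol(M) > 1 && qr(M)$rank < ncol(M))
    warning("level-0 prediction columns are collinear; ",
            "weights are unidentifiable and reflect the prior")
  set.seed(derive_seed(seed, 42))
  cache <- new.env(parent = emptyenv())
  cache$AtA <- Matrix::crossprod(A)
  cache$sym <- NULL

  if (is.null(fixed_hyperparameters)) {
    res <- tryCatch(lm.fit(M, g)$residuals, error = function(e) g)
    s0 <- max(sd(res), 0.05)
    init <- theta_pack(s0 / sqrt(2), max(grid$n_cols / 4, 1.5), 0.5,
                       s0 / sqrt(2))
    opt <- optim(init, neg_log_marginal, A = A, M = M, gv = g,
                 grid = grid, n_years = n_years, priors = priors,
                 cache = cache, method = "Nelder-Mead",
                 control = list(maxit = 300, reltol = 1e-7))
    theta_hat <- opt$par
    H <- tryCatch(optimHess(theta_hat, neg_log_marginal, A = A, M = M,
                            gv = g, grid = grid, n_years = n_years,
                            priors = priors, cache = cache),
                  error = function(e) diag(1e4, 4))
    ev <- eigen((H + t(H)) / 2, symmetric = TRUE)
    ev$values <- pmax(ev$values, 1e-4)
    theta_cov <- ev$vectors %*% diag(1 / ev$values) %*% t(ev$vectors)
    Lt <- chol(theta_cov)
    # draws reuse a reduced set of hyperparameter samples: each distinct
    # theta costs a sparse factorisation, (w, f) draws are cheap. Samples
    # come from a multivariate t centred at the mode - the usual defensive
    # choice guarding against Laplace underdispersion.
    n_theta <- min(n_draws, 40L)
    tdf <- theta_tail_df
    theta_set <- matrix(theta_hat, n_theta, 4, byrow = TRUE) +
      (matrix(rnorm(n_theta * 4), n_theta, 4) %*% Lt) *
        sqrt(tdf / rchisq(n_theta, tdf))
    convergence <- opt$convergence
    marg_ll <- -opt$value
  } else {
    fh <- fixed_hyperparameters
    theta_hat <- theta_pack(fh$field_sd, fh$range_cells, fh$rho, fh$sigma)
    n_theta <- 1L
    theta_set <- matrix(theta_hat, 1, 4)
    convergence <- 0L
    marg_ll <- NA_real_
  }
  theta_idx <- rep(seq_len(n_theta), length.out = n_draws)

  # analytic posterior means at the hyperparameter mode
  ws <- stack_workspace(theta_hat, A, M, g, grid, n_years, cache)
  Breg <- ws$B + diag(1e-10, ncol(ws$B))
  w_map <- nnls_solve(Breg, ws$b)
  f_map <- as.vector(Matrix::solve(
    ws$chP, Matrix::crossprod(A, g - M %*% w_map))) / ws$s2

  p <- ncol(M)
  w_draws <- matrix(NA_real_, n_draws, p, dimnames = list(NULL, colnames(M)))
  psi_draws <- matrix(NA_real_, n_draws, 3,
                      dimnames = list(NULL, c("field_sd", "range_cells",
                                              "rho")))
  sigma_draws <- numeric(n_draws)
  f_draws <- matrix(NA_real_, n_draws, nlat)
  w_cond_mean <- matrix(NA_real_, n_theta, p)
  w_cond_sd <- matrix(NA_real_, n_theta, p)
  f_cond_mean <- matrix(NA_real_, n_theta, nlat)
  for (t_i in seq_len(n_theta)) {
    th <- theta_set[t_i, ]
    wd <- if (all(th == theta_hat)) ws else
      tryCatch(stack_workspace(th, A, M, g, grid, n_years, cache),
               error = function(e) NULL)
    if (is.null(wd)) wd <- ws
    pr <- wd$pr
    Bd <- wd$B + diag(1e-10, p)
    Cd <- tryCatch(solve(Bd), error = function(e) diag(1e6, p))
    wmean <- as.vector(Cd %*% wd$b)
    w_cond_mean[t_i, ] <- wmean
    w_cond_sd[t_i, ] <- sqrt(pmax(diag(Cd), 0))
    # conditional field mean given theta (weights marginalised: linear in w)
    f_cond_mean[t_i, ] <- as.vector(Matrix::solve(
      wd$chP, Matrix::crossprod(A, g - as.vector(M %*% wmean)))) / wd$s2
    w_start <- nnls_solve(Bd, wd$b)
    for (d in which(theta_idx == t_i)) {
      w <- rtruncnorm_nonneg(wmean, Cd, Bd, start = w_start)
      r <- g - as.vector(M %*% w)
      fmean <- as.vector(Matrix::solve(wd$chP,
                                       Matrix::crossprod(A, r))) / wd$s2
      z <- rnorm(nlat)
      fdev <- as.vector(Matrix::solve(
        wd$chP, Matrix::solve(wd$chP, z, system = "Lt"), system = "Pt"))
      w_draws[d, ] <- w
      psi_draws[d, ] <- c(pr$sd, pr$range_cells, pr$rho)
      sigma_draws[d] <- pr$sigma
      f_draws[d, ] <- fmean + fdev
    }
  }

  structure(list(
    w_draws = w_draws, psi_draws = psi_draws, sigma_draws = sigma_draws,
    f_draws = f_draws, w_cond_mean = w_cond_mean, w_cond_sd = w_cond_sd,
    f_cond_mean = f_cond_mean, w_map = w_map, f_map = f_map,
    theta_map = theta_unpack(theta_hat), marg_loglik = marg_ll,
    convergence = convergence, grid = grid, n_years = n_years,
    cell = cell, year_idx = year_idx, model_names = colnames(M),
    labels = g, oof_matrix = M, priors = priors, n_draws = n_draws),
    class = "stack_posterior")
}

#' @export
print.stack_posterior <- function(x, ...) {
  cat("stack_posterior:", length(x$labels), "observations,",
      x$n_draws, "draws\n")
  cat("  weights (posterior mean):",
      paste(sprintf("%s=%.3f", x$model_names, colMeans(x$w_draws)),
            collapse = ", "), "\n")
  cat(sprintf("  field sd %.3f, range %.2f cells, rho %.3f, sigma %.3f (MAP)\n",
              x$theta_map$sd, x$theta_map$range_cells, x$theta_map$rho,
              x$theta_map$sigma))
  invisible(x)
}

#' Credible intervals of the stacking weights
#'
#' Rao-Blackwellised interval estimates: conditional on each hyperparameter
#' draw the weight posterior is multivariate normal (truncated at zero), so
#' when the truncation mass is negligible the marginal quantile is the
#' quantile of a mixture of analytic normals over the hyperparameter set -
#' free of weight-draw Monte Carlo noise. When truncation is material for
#' any hyperparameter draw the empirical draw quantiles are used instead.
#'
#' @param posterior A `stack_posterior`.
#' @param probs Quantile probabilities (default a central 95% interval).
#' @return Matrix `length(probs) x p` of weight quantiles.
#' @export
weight_intervals <- function(posterior, probs = c(0.025, 0.975)) {
  p <- ncol(posterior$w_draws)
  out <- matrix(NA_real_, length(probs), p,
                dimnames = list(as.character(probs),
                                posterior$model_names))
  for (j in seq_len(p)) {
    mu <- posterior$w_cond_mean[, j]
    sd_j <- posterior$w_cond_sd[, j]
    usable <- !is.null(mu) && all(is.finite(mu)) && all(is.finite(sd_j)) &&
      all(pnorm(0, mu, pmax(sd_j, 1e-12)) < 1e-3)
    for (q in seq_along(probs)) {
      out[q, j] <- if (usable) mixture_quantile(mu, sd_j, probs[q])
      else quantile(posterior$w_draws[, j], probs[q], names = FALSE)
    }
  }
  out
}

#' Posterior summary table of the meta-model parameters
#'
#' Means and 95% credible intervals of the model weights, field
#' hyperparameters, and noise SD, in the shape used for reporting fitted
#' Gaussian-process regression parameters.
#'
#' @param object A `stack_posterior`.
#' @param ... Unused.
#' @return Data frame with `parameter`, `mean`, `lower`, `upper`.
#' @export
summary.stack_posterior <- function(object, ...) {
  draws <- cbind(object$w_draws,
                 object$psi_draws,
                 sigma = object$sigma_draws)
  colnames(draws)[seq_along(object$model_names)] <-
    paste0("w.", object$model_names)
  out <- data.frame(parameter = colnames(draws),
                    mean = colMeans(draws),
                    lower = apply(draws, 2, quantile, 0.025),
                    upper = apply(draws, 2, quantile, 0.975),
                    row.names = NULL)
  wi <- weight_intervals(object)  # Rao-Blackwellised weight endpoints
  p <- ncol(object$w_draws)
  out$lower[seq_len(p)] <- wi[1, ]
  out$upper[seq_len(p)] <- wi[2, ]
  out
}

#' Predict the mortality surface from a fitted meta-model
#'
#' For each posterior draw, combines the weighted in-sample level-0
#' predictions at every pixel with the latent-field draw and back-transforms
#' to the natural (proportional-mortality) scale. The predictive mean
#' surface excludes the observation-noise term: it maps mean resistance,
#' not noisy replicate bioassays.
#'
#' @param posterior A `stack_posterior`.
#' @param insample_matrix `(n_cells * n_years) x p` matrix of in-sample
#'   level-0 predictions at pixels, rows ordered `(year-1)*n_cells + cell`.
#' @param n_draws Number of posterior draws to use (default all); a warning
#'   is issued below 100 (unstable credible intervals).
#' @param c,n_ref Back-transformation constants (see [inverse_transform()]).
#' @param keep_draws Whether to retain per-draw natural-scale surfaces
#'   (needed by the map summary operations).
#' @return Object of class `prediction_surface` with `n_cells x n_years`
#'   matrices `mean`, `lower`, `upper`, `width` (NA outside the mask) and,
#'   optionally, `draws`.
#' @export
predict_stack <- function(posterior, insample_matrix, n_draws = NULL,
                          c = 0.5, n_ref = 100, keep_draws = TRUE) {
  M <- as.matrix(insample_matrix)
  grid <- posterior$grid
  nlat <- n_cells(grid) * posterior$n_years
  stopifnot(nrow(M) == nlat, ncol(M) == ncol(posterior$w_draws))
  D <- if (is.null(n_draws)) posterior$n_draws else min(n_draws,
                                                        posterior$n_draws)
  if (D < 100)
    warning("fewer than 100 posterior draws: credible intervals unstable")
  eta <- tcrossprod(posterior$w_draws[seq_len(D), , drop = FALSE], M) +
    posterior$f_draws[seq_len(D), , drop = FALSE]
  nat <- inverse_transform(eta, c, n_ref)
  mean_s <- colMeans(nat)
  lower <- apply(nat, 2, quantile, 0.025)
  upper <- apply(nat, 2, quantile, 0.975)
  mask <- rep(as.vector(t(grid$mask)), posterior$n_years)
  mean_s[!mask] <- NA; lower[!mask] <- NA; upper[!mask] <- NA
  shape <- function(x) matrix(x, n_cells(grid), posterior$n_years)
  structure(list(grid = grid, years = grid$years,
                 mean = shape(mean_s), lower = shape(lower),
                 upper = shape(upper), width = shape(upper - lower),
                 draws = if (keep_draws) nat else NULL,
                 n_draws = D, c = c, n_ref = n_ref),
            class = "prediction_surface")
}

#' Predictive distribution at new observations
#'
#' The predictive distribution for a new observation includes the noise
#' variance `sigma^2` (the measurement error of a replicate bioassay), so
#' the probability integral transform (PIT) value is the mixture-of-normals
#' predictive CDF evaluated at the observed transformed label.
#'
#' @param posterior A `stack_posterior` fitted without these observations.
#' @param m_new `n x p` matrix of level-0 predictions for the new
#'   observations.
#' @param cell,year_idx Pixel and year indices of the new observations.
#' @param y Observed transformed labels.
#' @return Object of class `predictive_density`: data frame fields `mean`,
#'   `var`, `pit` plus draw-level components for interval computations.
#' @export
predictive_density <- function(posterior, m_new, cell, year_idx, y) {
  m_new <- as.matrix(m_new)
  n <- nrow(m_new)
  stopifnot(length(cell) == n, length(year_idx) == n, length(y) == n)
  idx <- (year_idx - 1L) * n_cells(posterior$grid) + cell
  mu <- tcrossprod(posterior$w_draws, m_new) +
    posterior$f_draws[, idx, drop = FALSE]              # D x n
  sig <- posterior$sigma_draws
  # Rao-Blackwellised predictive mean: exact conditional means per
  # hyperparameter draw, free of weight/field draw noise
  mean_i <- if (!is.null(posterior$f_cond_mean)) {
    colMeans(tcrossprod(posterior$w_cond_mean, m_new) +
               posterior$f_cond_mean[, idx, drop = FALSE])
  } else colMeans(mu)
  var_i <- mean(sig^2) + colMeans(mu^2) - colMeans(mu)^2
  pit <- vapply(seq_len(n), function(i)
    mean(pnorm(y[i], mu[, i], sig)), numeric(1))
  structure(list(mean = mean_i, var = var_i, pit = pit,
                 mu_draws = mu, sigma_draws = sig, y = y),
            class = "predictive_density")
}

# Quantile of the mixture-of-normals predictive distribution; sd_draws = 0
# gives quantiles of the mean draws.
mixture_quantile <- function(mu_d, sd_d, prob) {
  if (all(sd_d == 0)) return(quantile(mu_d, prob, names = FALSE))
  lo <- min(mu_d) - 8 * max(sd_d)
  hi <- max(mu_d) + 8 * max(sd_d)
  uniroot(function(q) mean(pnorm(q, mu_d, sd_d)) - prob, c(lo, hi),
          tol = 1e-9)$root
}
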