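# Shared desk-scale fixtures, built in code at test time.

tiny_grid <- function(n = 6, years = 2005:2006, cellsize = 0.5) {
  grid_definition(0, n * cellsize, cellsize = cellsize, n_cols = n,
                  n_rows = n, years = years)
}

small_sim_config <- function(seed = 1L, ...) {
  args <- list(
    grid = grid_definition(-10, 12, cellsize = 1 / 24, n_cols = 12,
                           n_rows = 12, years = 2005:2007),
    n_covariates = 3, n_monthly_covariates = 1,
    field_sd = 0.5, field_range = 0.15, temporal_rho = 0.8,
    noise_sd = 0.3, n_sites = 50, n_obs = 200, n_vgsc = 25, seed = seed)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

fast_specs <- list(gbt = list(nrounds = 30, max_depth = 2),
                   rf = list(ntree = 30),
                   bgam = list(mstop = 40))

# A degenerate zero-variance posterior test double: every draw identical.
constant_posterior <- function(grid, value = 0, sigma = 0.2, n_draws = 120,
                               n_models = 2) {
  nlat <- grid$n_rows * grid$n_cols * length(grid$years)
  structure(list(
    w_draws = matrix(1 / n_models, n_draws, n_models,
                     dimnames = list(NULL, paste0("m", seq_len(n_models)))),
    psi_draws = matrix(rep(c(0.5, 3, 0.5), each = n_draws), n_draws, 3,
                       dimnames = list(NULL, c("field_sd", "range_cells",
                                               "rho"))),
    sigma_draws = rep(sigma, n_draws),
    f_draws = matrix(value, n_draws, nlat),
    w_map = rep(1 / n_models, n_models), f_map = rep(value, nlat),
    theta_map = list(sd = 0.5, range_cells = 3, rho = 0.5, sigma = sigma),
    marg_loglik = NA_real_, convergence = 0L, grid = grid,
    n_years = length(grid$years), cell = integer(0), year_idx = integer(0),
    model_names = paste0("m", seq_len(n_models)), labels = numeric(0),
    oof_matrix = matrix(numeric(0), 0, n_models), priors = list(),
    n_draws = n_draws), class = "stack_posterior")
}

# Draws from the same separable GMRF class the meta-model assumes, plus
# known-signal design columns: the correctly specified world for the
# meta-model (no trend, no intercept).
simulate_stack_world <- function(n = 800, grid = NULL, sd = 0.6, range = 5,
                                 rho = 0.8, sigma = 0.35,
                                 w = c(0.5, 0.3, 0.2), seed = 1L) {
  set.seed(seed)
  if (is.null(grid))
    grid <- grid_definition(-10, 12, n_cols = 20, n_rows = 20,
                            years = 2005:2010)
  nc <- grid$n_rows * grid$n_cols
  ny <- length(grid$years)
  Q <- resistmap:::st_precision(grid$n_rows, grid$n_cols, ny, sd, range, rho)
  f <- as.vector(resistmap:::sample_gmrf(Q, 1))
  cell <- sample.int(nc, n, TRUE)
  yi <- sample.int(ny, n, TRUE)
  idx <- (yi - 1L) * nc + cell
  M <- matrix(rnorm(n * length(w)), n, length(w),
              dimnames = list(NULL, paste0("m", seq_along(w))))
  g <- as.vector(M %*% w) + f[idx] + rnorm(n, 0, sigma)
  list(grid = grid, cell = cell, year_idx = yi, idx = idx, M = M, g = g,
       f = f, truth = list(sd = sd, range = range, rho = rho,
                           sigma = sigma, w = w))
}
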