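# Dense closed-form oracles: with hyperparameters fixed and the positivity
# constraint inactive, the sparse implementation must agree with textbook
# Gaussian conditioning / GLS to high precision.

dense_oracle <- function(world, fh) {
  grid <- world$grid
  nc <- grid$n_rows * grid$n_cols
  ny <- length(grid$years)
  Qs <- resistmap:::spatial_precision(grid$n_rows, grid$n_cols,
                                      fh$range_cells)
  Rt <- outer(seq_len(ny), seq_len(ny), function(a, b) fh$rho^abs(a - b))
  K <- fh$field_sd^2 * kronecker(Rt, solve(as.matrix(Qs)))
  Sig <- K[world$idx, world$idx] + diag(fh$sigma^2, length(world$g))
  Si <- solve(Sig)
  M <- world$M
  w <- solve(t(M) %*% Si %*% M, t(M) %*% Si %*% world$g)
  f <- K[, world$idx] %*% Si %*% (world$g - M %*% w)
  list(w = as.vector(w), f = as.vector(f))
}

test_that("posterior means equal dense GLS / Gaussian conditioning", {
  world <- simulate_stack_world(n = 40, grid = tiny_grid(6, 2005:2006),
                                sd = 0.5, range = 3, rho = 0.6,
                                sigma = 0.3, w = c(0.7, 0.4), seed = 51)
  fh <- list(field_sd = 0.5, range_cells = 3, rho = 0.6, sigma = 0.3)
  oracle <- dense_oracle(world, fh)
  expect_true(all(oracle$w > 0))  # constraint inactive
  fit <- fit_stack(world$g, world$M, world$cell, world$year_idx,
                   world$grid, n_draws = 5, seed = 1,
                   fixed_hyperparameters = fh)
  expect_equal(fit$w_map, oracle$w, tolerance = 1e-6)
  expect_equal(fit$f_map, oracle$f, tolerance = 1e-6)
})

test_that("a truth-tracking column dominates a noise column", {
  set.seed(52)
  grid <- tiny_grid(8, 2005:2006)
  n <- 150
  nc <- 64; ny <- 2
  cell <- sample.int(nc, n, TRUE); yi <- sample.int(ny, n, TRUE)
  g <- rnorm(n)
  M <- cbind(good = g + rnorm(n, 0, 0.05), noise = rnorm(n))
  fit <- fit_stack(g, M, cell, yi, grid, n_draws = 80, seed = 2,
                   fixed_hyperparameters = list(field_sd = 1e-3,
                                                range_cells = 2, rho = 0.5,
                                                sigma = 0.1))
  wm <- colMeans(fit$w_draws)
  expect_gt(wm["good"], 0.9)
  expect_lt(wm["noise"], 0.1)
  expect_true(all(fit$w_draws >= 0))
})

test_that("all-zero labels give near-zero predictions everywhere", {
  grid <- tiny_grid(5, 2005)
  set.seed(53)
  n <- 30
  cell <- sample.int(25, n, TRUE)
  M <- cbind(rnorm(n), rnorm(n))
  fit <- fit_stack(rep(0, n), M, cell, rep(1L, n), grid, n_draws = 120,
                   seed = 3,
                   fixed_hyperparameters = list(field_sd = 0.3,
                                                range_cells = 2, rho = 0.5,
                                                sigma = 0.2))
  surf <- predict_stack(fit, matrix(0, 25, 2))
  expect_lt(max(abs(surf$mean - 0.5), na.rm = TRUE), 0.06)  # 0 maps to 0.5
})

test_that("collinear level-0 columns trigger the identifiability warning", {
  grid <- tiny_grid(4, 2005)
  n <- 20
  set.seed(54)
  m1 <- rnorm(n)
  expect_warning(
    fit_stack(rnorm(n), cbind(m1, m1), sample.int(16, n, TRUE),
              rep(1L, n), grid, n_draws = 5, seed = 4,
              fixed_hyperparameters = list(field_sd = 0.3, range_cells = 2,
                                           rho = 0.5, sigma = 0.2)),
    "collinear")
})

test_that("prediction surfaces respect their invariants", {
  grid <- tiny_grid(5, 2005:2006)
  post <- constant_posterior(grid, value = 0.4)
  Mp <- matrix(0.8, 50, 2)
  surf <- predict_stack(post, Mp)
  # degenerate zero-variance posterior: zero CI width, mean = point value
  expect_equal(max(surf$width, na.rm = TRUE), 0)
  expect_equal(surf$mean[1, 1], inverse_transform(0.8 + 0.4))
  expect_warning(predict_stack(post, Mp, n_draws = 50), "100")

  world <- simulate_stack_world(n = 60, grid = grid, sd = 0.5, range = 2,
                                rho = 0.5, sigma = 0.3, w = c(0.5, 0.3),
                                seed = 55)
  fit <- fit_stack(world$g, world$M, world$cell, world$year_idx, grid,
                   n_draws = 150, seed = 5,
                   fixed_hyperparameters = list(field_sd = 0.5,
                                                range_cells = 2, rho = 0.5,
                                                sigma = 0.3))
  surf2 <- predict_stack(fit, matrix(0, 50, 2))
  expect_true(all(surf2$lower <= surf2$mean & surf2$mean <= surf2$upper,
                  na.rm = TRUE))
  expect_true(all(surf2$mean >= 0 & surf2$mean <= 1, na.rm = TRUE))
})

test_that("uncertainty grows away from the data", {
  # clustered sites in the NW corner; the far SE pixel must not have a
  # narrower interval than the most data-dense pixel (10 seeds)
  grid <- tiny_grid(8, 2005)
  nc <- 64
  wins <- 0
  for (s in 1:10) {
    set.seed(600 + s)
    n <- 80
    cell <- sample(c(1:3, 9:11, 17:19), n, TRUE)  # NW corner cells
    g <- rnorm(n, 0, 0.5)
    M <- cbind(rnorm(n), rnorm(n))
    fit <- fit_stack(g, M, cell, rep(1L, n), grid, n_draws = 150, seed = s,
                     fixed_hyperparameters = list(field_sd = 0.6,
                                                  range_cells = 2,
                                                  rho = 0.5, sigma = 0.3))
    surf <- predict_stack(fit, matrix(0, nc, 2))
    dense_cell <- as.integer(names(which.max(table(cell))))
    wins <- wins + (surf$width[nc, 1] >= surf$width[dense_cell, 1])
  }
  expect_gte(wins, 9)
})

test_that("Rao-Blackwellised weight intervals agree with draw quantiles", {
  world <- simulate_stack_world(n = 120, grid = tiny_grid(8, 2005:2006),
                                sd = 0.5, range = 3, rho = 0.6,
                                sigma = 0.3, w = c(0.7, 0.4), seed = 61)
  fit <- fit_stack(world$g, world$M, world$cell, world$year_idx,
                   world$grid, n_draws = 400, seed = 6,
                   fixed_hyperparameters = list(field_sd = 0.5,
                                                range_cells = 3, rho = 0.6,
                                                sigma = 0.3))
  wi <- weight_intervals(fit)
  # with one fixed theta the mixture is a single analytic normal; the
  # 400-draw empirical quantiles must agree to sampling accuracy
  for (j in 1:2) {
    emp <- quantile(fit$w_draws[, j], c(0.025, 0.975), names = FALSE)
    expect_equal(unname(wi[, j]), emp, tolerance = 0.05)
  }
  expect_true(all(wi[1, ] < wi[2, ]))
})

test_that("predictive density carries noise variance and centred PIT", {
  grid <- tiny_grid(5, 2005)
  post <- constant_posterior(grid, value = 0.2, sigma = 0.3)
  m_new <- matrix(0.6, 3, 2)
  mu_expected <- 0.6 + 0.2
  pd <- predictive_density(post, m_new, cell = c(1, 5, 9), year_idx = rep(1L, 3),
                           y = c(mu_expected, mu_expected + 0.3,
                                 mu_expected - 0.3))
  expect_equal(pd$pit[1], 0.5)              # observation at predictive mean
  expect_gt(pd$pit[2], 0.5)
  expect_lt(pd$pit[3], 0.5)
  expect_equal(pd$mean, rep(mu_expected, 3))
  # predictive variance >= posterior mean noise variance
  expect_true(all(pd$var >= mean(post$sigma_draws^2) - 1e-12))
})
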