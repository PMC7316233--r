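# Monte-Carlo tolerances follow the generator's stated contracts.

moran_i <- function(v, n_rows, n_cols) {
  # brute-force Moran's I on the 4-neighbour lattice
  m <- matrix(v, n_rows, n_cols, byrow = TRUE)
  z <- m - mean(m)
  num <- 0; W <- 0
  for (r in seq_len(n_rows)) for (cl in seq_len(n_cols)) {
    for (d in list(c(0, 1), c(1, 0))) {
      r2 <- r + d[1]; c2 <- cl + d[2]
      if (r2 <= n_rows && c2 <= n_cols) {
        num <- num + 2 * z[r, cl] * z[r2, c2]
        W <- W + 2
      }
    }
  }
  (length(v) / W) * num / sum(z^2)
}

test_that("simulated covariates are lag-expanded, reproducible, and smooth", {
  g <- tiny_grid(10, years = 2005:2006)
  # range of 3 cells on this 0.5-degree grid
  st <- simulate_covariates(g, n_covariates = 5, n_monthly = 0,
                            field_range = 1.5, seed = 5)
  expect_equal(dim(st$layers)[3], 20)  # 5 covariates x 4 lags
  expect_equal(sum(grepl("_lag3$", st$layer_names)), 5)
  st2 <- simulate_covariates(g, n_covariates = 5, n_monthly = 0,
                             field_range = 1.5, seed = 5)
  expect_identical(st$layers, st2$layers)
  # lag-l layer at year t equals the lag-0 layer l years earlier
  st3 <- simulate_covariates(g, 2, 0, seed = 9)
  expect_identical(st3$layers[, 2, "cov01_lag1"], st3$layers[, 1, "cov01_lag0"])
  # spatial autocorrelation: Moran's I positive for every layer
  mi <- vapply(seq_len(dim(st$layers)[3]),
               function(k) moran_i(st$layers[, 1, k], 10, 10), numeric(1))
  expect_true(all(mi > 0))
})

test_that("true-surface field matches its configured moments", {
  # marginal sd over >= 2,500 pixels within 10%
  cfg <- small_sim_config(
    grid = grid_definition(-10, 12, cellsize = 1 / 24, n_cols = 26,
                           n_rows = 26, years = 2005:2008),
    field_sd = 0.6, n_covariates = 3)
  tr <- simulate_true_surface(cfg, seed = 21)
  expect_equal(dim(tr$truth), c(676, 4))
  expect_equal(sd(as.vector(tr$field)), 0.6, tolerance = 0.1)
  # field_sd -> 0 with zero weights gives a constant surface per year
  cfg0 <- small_sim_config(field_sd = 1e-6, weight_truth = c(0, 0, 0))
  tr0 <- simulate_true_surface(cfg0, seed = 3)
  expect_lt(max(abs(tr0$truth[, 1] - mean(tr0$truth[, 1]))), 1e-3)
})

test_that("field lag-1 year correlation matches temporal_rho", {
  # 500 replicate fields on a small grid; correlation within 0.05
  set.seed(31)
  Q <- resistmap:::st_precision(8, 8, 2, field_sd = 1, range_cells = 2,
                                rho = 0.7)
  draws <- resistmap:::sample_gmrf(Q, 500)  # 128 x 500
  cors <- vapply(seq_len(64), function(px)
    cor(draws[px, ], draws[px + 64, ]), numeric(1))
  expect_equal(mean(cors), 0.7, tolerance = 0.05)
})

test_that("observations reflect the truth through the binomial chain", {
  cfg <- small_sim_config(noise_sd = 0, n_obs = 1000,
                          n_tested_mean = 4000, n_tested_size = 50,
                          weight_truth = c(0, 0, 0), field_sd = 1e-6,
                          trend_slope = 0, baseline = 0)  # truth p = 0.5
  tr <- simulate_true_surface(cfg, seed = 41)
  obs <- simulate_observations(tr, cfg, seed = 42)
  # per-observation: within 2/sqrt(n) of the back-transformed truth
  p_true <- inverse_transform(0, cfg$c, cfg$n_ref)
  dev <- abs(obs$bioassay$mortality - p_true)
  expect_gt(mean(dev <= 2 / sqrt(obs$bioassay$n_tested)), 0.93)
  # CLT bound on the mean of 1,000 observations at truth 0.5
  expect_gt(mean(obs$bioassay$mortality), 0.48)
  expect_lt(mean(obs$bioassay$mortality), 0.52)
  # seed-determinism of the full table
  obs2 <- simulate_observations(tr, cfg, seed = 42)
  expect_identical(obs$bioassay, obs2$bioassay)
  expect_identical(obs$allele, obs2$allele)
})

test_that("generated tables satisfy the data-model invariants", {
  cfg <- small_sim_config(seed = 8)
  dat <- simulate_dataset(cfg)
  expect_silent(resistmap:::validate_observations(dat$bioassay, "bioassay",
                                                  grid = cfg$grid))
  expect_silent(resistmap:::validate_observations(dat$allele, "allele"))
  expect_true(all(dat$bioassay$n_tested >= 10))
  # allele frequency decreases with mortality (shared latent truth)
  expect_true(mean(dat$allele$frequency) > 0)
  # site clustering: observations reuse a limited set of sites
  expect_lte(length(unique(dat$bioassay$site_id)), cfg$n_sites)
})
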