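#' Configuration for the synthetic bioassay world
#'
#' Describes the generative world the pipeline is tested against: a smooth
#' covariate-driven resistance signal plus a separable spatiotemporal GMRF,
#' observed through noisy binomial bioassays at spatially clustered sites.
#' Defaults are chosen once to emulate the statistical structure of real
#' susceptibility-test databases (strongly clustered sampling, WHO-test
#' sample sizes around 80 mosquitoes, a marked 2005-onwards rise in
#' resistance) and are documented in the methods vignette.
#'
#' @param grid A [grid_definition()]; default a 20 x 20 lattice of
#'   2.5 arc-minute cells over 6 years.
#' @param n_covariates Number of yearly covariates (lag-expanded 0-3).
#' @param n_monthly_covariates Covariates emitted as 12 monthly layers/year.
#' @param field_sd Marginal SD of the latent spatiotemporal field
#'   (transformed scale).
#' @param field_range Spatial correlation range in degrees.
#' @param temporal_rho AR(1) correlation of the field across years.
#' @param noise_sd Bioassay measurement-error SD on the transformed scale
#'   (acting on top of binomial sampling error).
#' @param weight_truth Nonnegative true weights of the simulated level-0
#'   signals that compose the mean surface.
#' @param covariate_effect `"nonlinear"` (smooth nonlinear functions of the
#'   covariates) or `"linear"`.
#' @param trend_slope Yearly change of the transformed-mortality baseline;
#'   the negative default mimics the 2005-2017 resistance rise.
#' @param baseline Transformed-scale intercept at the middle modelled year.
#' @param n_sites Number of sampling sites.
#' @param n_obs Number of bioassay observations.
#' @param n_vgsc Number of target-site allele-frequency observations.
#' @param cluster_size Mean sites per cluster of the Poisson (Thomas)
#'   cluster process generating site locations.
#' @param cluster_sd Within-cluster Gaussian spread, degrees.
#' @param n_tested_mean,n_tested_size Shifted negative-binomial sample-size
#'   distribution: `n = 10 + NB(mu = n_tested_mean - 10, size =
#'   n_tested_size)`, mean ~ 80 as in WHO tube tests.
#' @param c,n_ref Transformation constants (see [transform_label()]).
#' @param seed Integer seed making the whole generator deterministic.
#' @return A `sim_config` list.
#' @export
sim_config <- function(grid = grid_definition(-10, 12, n_cols = 20,
                                              n_rows = 20,
                                              years = 2005:2010),
                       n_covariates = 5, n_monthly_covariates = 1,
                       field_sd = 0.6, field_range = 0.2,
                       temporal_rho = 0.8, noise_sd = 0.3,
                       weight_truth = c(0.5, 0.3, 0.2),
                       covariate_effect = c("nonlinear", "linear"),
                       trend_slope = -0.24, baseline = 2.0,
                       n_sites = 150, n_obs = 800, n_vgsc = 60,
                       cluster_size = 6, cluster_sd = 0.05,
                       n_tested_mean = 80, n_tested_size = 5,
                       c = 0.5, n_ref = 100, seed = 1L) {
  covariate_effect <- match.arg(covariate_effect)
  stopifnot(field_sd > 0, field_range > 0, abs(temporal_rho) < 1,
            noise_sd >= 0, all(weight_truth >= 0),
            n_covariates >= length(weight_truth), n_sites >= 1, n_obs >= 1)
  structure(as.list(environment()), class = "sim_config")
}

range_in_cells <- function(grid, field_range) {
  max(field_range / grid$cellsize, 1e-6)
}

new_covariate_stack <- function(grid, years, layers, layer_names,
                                monthly = NULL, monthly_names = NULL) {
  dimnames(layers) <- list(NULL, NULL, layer_names)
  structure(list(grid = grid, years = as.integer(years), layers = layers,
                 layer_names = layer_names, monthly = monthly,
                 monthly_names = monthly_names),
            class = "covariate_stack")
}

#' Simulate a gridded covariate stack
#'
#' Draws each covariate as a smooth spatial random surface evolving slowly
#' across years (a unit-variance GMRF with AR(1) correlation 0.9). Yearly
#' covariates are expanded with 0-3-year lags (base years are simulated three
#' years before the first modelled year so lagged layers are exact, not
#' clamped). Monthly covariates are emitted as 12 layers per year for
#' downstream principal-component reduction.
#'
#' @param grid A [grid_definition()].
#' @param n_covariates Number of yearly covariates.
#' @param n_monthly Number of monthly covariates.
#' @param field_range Spatial range of the covariate surfaces, degrees.
#' @param lags Integer lags to expand (default `0:3`).
#' @param seed Optional seed.
#' @return A `covariate_stack` with `length(lags) * n_covariates` lagged
#'   yearly layers (named `covXX_lagL`) plus raw monthly layers.
#' @export
simulate_covariates <- function(grid, n_covariates = 5, n_monthly = 1,
                                field_range = 0.3, lags = 0:3,
                                seed = NULL) {
  stopifnot(n_covariates >= 1, n_monthly >= 0)
  if (!is.null(seed)) set.seed(seed)
  years <- grid$years
  max_lag <- max(lags)
  base_years <- (min(years) - max_lag):max(years)
  nb <- length(base_years)
  nc <- n_cells(grid)
  Q <- st_precision(grid$n_rows, grid$n_cols, nb, field_sd = 1,
                    range_cells = range_in_cells(grid, field_range),
                    rho = 0.9)
  base <- array(sample_gmrf(Q, n_covariates),
                dim = c(nc, nb, n_covariates))
  n_layers <- n_covariates * length(lags)
  layers <- array(NA_real_, dim = c(nc, length(years), n_layers))
  layer_names <- character(n_layers)
  k <- 0
  for (j in seq_len(n_covariates)) {
    for (l in lags) {
      k <- k + 1
      layer_names[k] <- sprintf("cov%02d_lag%d", j, l)
      layers[, , k] <- base[, match(years - l, base_years), j]
    }
  }
  monthly <- NULL; monthly_names <- NULL
  if (n_monthly > 0) {
    monthly <- array(NA_real_, dim = c(nc, length(years), 12, n_monthly))
    monthly_names <- sprintf("mcov%02d", seq_len(n_monthly))
    for (j in seq_len(n_monthly)) {
      mb <- array(sample_gmrf(Q, 1), dim = c(nc, nb))[, match(years, base_years)]
      amp <- 0.5 + 0.5 * abs(as.vector(sample_gmrf(spatial_precision(
        grid$n_rows, grid$n_cols, range_in_cells(grid, field_range)), 1)))
      for (m in 1:12) {
        monthly[, , m, j] <- mb + amp * sin(2 * pi * m / 12) +
          0.05 * rnorm(nc)
      }
    }
  }
  new_covariate_stack(grid, years, layers, layer_names, monthly,
                      monthly_names)
}

# Standardised smooth signals built from the lag-0 covariate layers; these
# play the role of the level-0 model predictions in the generative world.
truth_signals <- function(stack, n_signals, effect = "nonlinear") {
  funs <- list(function(x) sin(pi * x / 2),
               function(x) x^2,
               function(x) tanh(1.5 * x),
               function(x) abs(x),
               function(x) x)
  lag0 <- grep("_lag0$", stack$layer_names)
  stopifnot(length(lag0) >= n_signals)
  nc <- dim(stack$layers)[1]; ny <- dim(stack$layers)[2]
  sig <- array(NA_real_, dim = c(nc, ny, n_signals))
  for (p in seq_len(n_signals)) {
    x <- stack$layers[, , lag0[p]]
    s <- if (effect == "linear") x else funs[[(p - 1) %% length(funs) + 1]](x)
    sig[, , p] <- (s - mean(s)) / sd(as.vector(s))
  }
  sig
}

#' Simulate the true transformed resistance surface
#'
#' The truth is `baseline + trend + sum_p w_p * signal_p(covariates) +
#' f(s, t)` on the transformed (empirical-logit + IHS) scale, where `f` is a
#' separable Matern-type x AR(1) GMRF with marginal SD `field_sd`. The
#' negative default trend makes mortality decline over the modelled years,
#' mimicking the observed rise in resistance.
#'
#' @param cfg A [sim_config()].
#' @param stack Optional pre-simulated `covariate_stack`; generated from
#'   `cfg` when missing.
#' @param seed Optional seed (defaults to `cfg$seed`).
#' @return List with `truth` (`n_cells x n_years` matrix, transformed
#'   scale), `signals` (`n_cells x n_years x P`), `field`, `stack`, `cfg`.
#' @export
simulate_true_surface <- function(cfg, stack = NULL, seed = cfg$seed) {
  if (!is.null(seed)) set.seed(seed)
  grid <- cfg$grid
  if (is.null(stack))
    stack <- simulate_covariates(grid, cfg$n_covariates,
                                 cfg$n_monthly_covariates,
                                 field_range = cfg$field_range * 1.5,
                                 seed = NULL)
  years <- grid$years
  ny <- length(years)
  nc <- n_cells(grid)
  P <- length(cfg$weight_truth)
  signals <- truth_signals(stack, P, cfg$covariate_effect)
  f <- matrix(sample_gmrf(st_precision(grid$n_rows, grid$n_cols, ny,
                                       cfg$field_sd,
                                       range_in_cells(grid, cfg$field_range),
                                       cfg$temporal_rho), 1),
              nc, ny)
  trend <- cfg$baseline + cfg$trend_slope * (years - mean(years))
  truth <- matrix(rep(trend, each = nc), nc, ny) + f
  for (p in seq_len(P)) truth <- truth + cfg$weight_truth[p] * signals[, , p]
  list(truth = truth, signals = signals, field = f, stack = stack,
       cfg = cfg)
}

# Thomas cluster process for site locations restricted to masked-in cells.
sample_sites <- function(grid, n_sites, cluster_size, cluster_sd) {
  ext_lon <- c(grid$origin_lon, grid$origin_lon + grid$n_cols * grid$cellsize)
  ext_lat <- c(grid$origin_lat - grid$n_rows * grid$cellsize, grid$origin_lat)
  n_parents <- max(1L, round(n_sites / cluster_size))
  px <- runif(n_parents, ext_lon[1], ext_lon[2])
  py <- runif(n_parents, ext_lat[1], ext_lat[2])
  inside <- as.vector(t(grid$mask))
  lon <- numeric(n_sites); lat <- numeric(n_sites); cell <- integer(n_sites)
  for (i in seq_len(n_sites)) {
    repeat {
      k <- sample.int(n_parents, 1)
      x <- px[k] + rnorm(1, sd = cluster_sd)
      y <- py[k] + rnorm(1, sd = cluster_sd)
      cl <- point_to_cell(grid, x, y)
      if (!is.na(cl) && inside[cl]) {
        lon[i] <- x; lat[i] <- y; cell[i] <- cl
        break
      }
    }
  }
  data.frame(site_id = sprintf("site%04d", seq_len(n_sites)),
             lon = lon, lat = lat, cell = cell)
}

rn_tested <- function(n, mean, size, shift = 10) {
  shift + rnbinom(n, mu = mean - shift, size = size)
}

#' Simulate bioassay and allele-frequency observation tables
#'
#' Sites are drawn from a Poisson cluster process (heterogeneous sampling);
#' each observation draws a site, a year, an insecticide group and a sample
#' size, perturbs the transformed truth with Gaussian measurement noise
#' (`noise_sd`), back-transforms to a mortality probability, and observes a
#' binomial count. *Vgsc* allele frequencies are generated from a monotone
#' decreasing map of the same transformed truth (high resistance = low
#' mortality = high mutant frequency) plus noise.
#'
#' @param truth Output of [simulate_true_surface()] (or a bare
#'   `n_cells x n_years` matrix on the transformed scale).
#' @param cfg A [sim_config()].
#' @param seed Optional seed (defaults to `cfg$seed + 1`).
#' @return List with `bioassay` and `allele` data frames satisfying the
#'   data-model schemas, plus `sites`.
#' @export
simulate_observations <- function(truth, cfg, seed = cfg$seed + 1L) {
  if (!is.null(seed)) set.seed(seed)
  tr <- if (is.list(truth)) truth$truth else truth
  grid <- cfg$grid
  years <- grid$years
  sites <- sample_sites(grid, cfg$n_sites, cfg$cluster_size, cfg$cluster_sd)

  s_idx <- sample.int(nrow(sites), cfg$n_obs, replace = TRUE)
  y_idx <- sample.int(length(years), cfg$n_obs, replace = TRUE)
  insecticide <- sample(INSECTICIDES, cfg$n_obs, replace = TRUE,
                        prob = c(0.3, 0.25, 0.1, 0.1, 0.25))
  protocol <- sample(PROTOCOLS, cfg$n_obs, replace = TRUE,
                     prob = c(0.8, 0.2))
  z <- tr[cbind(sites$cell[s_idx], y_idx)] + rnorm(cfg$n_obs, 0, cfg$noise_sd)
  p <- inverse_transform(z, cfg$c, cfg$n_ref)
  n_tested <- rn_tested(cfg$n_obs, cfg$n_tested_mean, cfg$n_tested_size)
  mortality <- rbinom(cfg$n_obs, n_tested, p) / n_tested
  bio <- data.frame(site_id = sites$site_id[s_idx],
                    lon = sites$lon[s_idx], lat = sites$lat[s_idx],
                    year = years[y_idx], insecticide = insecticide,
                    protocol = protocol, n_tested = n_tested,
                    mortality = mortality)

  allele <- NULL
  if (cfg$n_vgsc > 0) {
    s_idx <- sample.int(nrow(sites), cfg$n_vgsc, replace = TRUE)
    y_idx <- sample.int(length(years), cfg$n_vgsc, replace = TRUE)
    zv <- -tr[cbind(sites$cell[s_idx], y_idx)] +
      rnorm(cfg$n_vgsc, 0, cfg$noise_sd)
    fq <- inverse_transform(zv, cfg$c, cfg$n_ref)
    n_alleles <- 2L * rn_tested(cfg$n_vgsc, 40, cfg$n_tested_size, shift = 10)
    allele <- data.frame(site_id = sites$site_id[s_idx],
                         lon = sites$lon[s_idx], lat = sites$lat[s_idx],
                         year = years[y_idx],
                         frequency = rbinom(cfg$n_vgsc, n_alleles, fq) /
                           n_alleles,
                         n_alleles = n_alleles)
  }
  list(bioassay = bio, allele = allele, sites = sites)
}

#' Simulate a complete synthetic dataset
#'
#' Convenience wrapper running [simulate_covariates()],
#' [simulate_true_surface()] and [simulate_observations()] under `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return List with `stack`, `truth` (full output of
#'   [simulate_true_surface()]), `bioassay`, `allele`, `sites`.
#' @export
simulate_dataset <- function(cfg) {
  set.seed(cfg$seed)
  stack <- simulate_covariates(cfg$grid, cfg$n_covariates,
                               cfg$n_monthly_covariates,
                               field_range = cfg$field_range * 1.5,
                               seed = NULL)
  truth <- simulate_true_surface(cfg, stack, seed = NULL)
  obs <- simulate_observations(truth, cfg, seed = NULL)
  c(list(stack = stack, truth = truth), obs)
}
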