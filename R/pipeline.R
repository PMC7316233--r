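# End-to-end pipeline: YAML config -> data (synthetic or files) ->
# transforms -> level-0 ensemble -> per-group GP meta-models -> prediction
# surfaces -> summaries (and optional cross-validation), all written to an
# artifact directory with a log of seeds and chosen hyperparameters.

pipeline_config_keys <- c("seed", "output_dir", "grid", "simulate",
                          "inputs", "transforms", "level0", "stack",
                          "predict", "validate", "summaries")

#' Load and validate a pipeline configuration
#'
#' @param config Path to a YAML file or an already-parsed list.
#' @return Validated config list with defaults filled in.
#' @export
read_pipeline_config <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  unknown <- setdiff(names(cfg), pipeline_config_keys)
  if (length(unknown))
    stop("config error: unknown key(s): ", paste(unknown, collapse = ", "))
  if (is.null(cfg$grid)) stop("config error: `grid` block is required")
  defaults <- list(
    seed = 1L,
    transforms = list(c = 0.5, n_ref = 100),
    level0 = list(K = 5, tune = FALSE,
                  specs = list(gbt = list(nrounds = 50, max_depth = 3),
                               rf = list(ntree = 50),
                               bgam = list(mstop = 80))),
    stack = list(n_draws = 150,
                 groups = list(pyrethroids = PYRETHROIDS, DDT = "DDT")),
    predict = list(insecticides = c("deltamethrin", "DDT"),
                   protocol = "WHO"),
    validate = list(enabled = FALSE, K = 10),
    summaries = list(threshold = 0.9))
  cfg <- utils::modifyList(defaults, cfg)
  if (cfg$level0$K < 2 || (isTRUE(cfg$validate$enabled) && cfg$validate$K < 2))
    stop("config error: cross-validation needs K >= 2")
  if (is.null(cfg$simulate) && is.null(cfg$inputs))
    stop("config error: either a `simulate` or an `inputs` block is required")
  cfg
}

config_grid <- function(gc) {
  years <- if (!is.null(gc$years$from)) gc$years$from:gc$years$to
           else as.integer(unlist(gc$years))
  grid_definition(gc$origin_lon, gc$origin_lat,
                  cellsize = gc$cellsize %||% (1 / 24),
                  n_cols = gc$n_cols, n_rows = gc$n_rows, years = years)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a directory of per-layer, per-year text rasters as a covariate stack
#'
#' Files must be named `<layer>_<year>.asc`; every layer must cover every
#' grid year.
#'
#' @param dir Directory of ESRI ASCII grids written by [write_raster()].
#' @param grid A [grid_definition()].
#' @return A `covariate_stack`.
#' @export
read_covariate_stack <- function(dir, grid) {
  files <- list.files(dir, pattern = "\\.asc$", full.names = TRUE)
  if (!length(files)) stop("no .asc rasters found in ", dir)
  base <- sub("\\.asc$", "", basename(files))
  year <- as.integer(sub(".*_([0-9]{4})$", "\\1", base))
  layer <- sub("_[0-9]{4}$", "", base)
  layers <- sort(unique(layer))
  arr <- array(NA_real_, dim = c(n_cells(grid), length(grid$years),
                                 length(layers)))
  for (i in seq_along(files)) {
    y <- match(year[i], grid$years)
    l <- match(layer[i], layers)
    if (is.na(y)) next
    arr[, y, l] <- read_raster(files[i])$values
  }
  if (anyNA(arr[as.vector(t(grid$mask)), , ]))
    stop("covariate stack has missing layer/year combinations")
  new_covariate_stack(grid, grid$years, arr, layers)
}

#' Run the full mapping pipeline
#'
#' Executes transforms, the level-0 ensemble, per-group meta-model fitting,
#' pixel prediction, summaries, and (optionally) cross-validation as
#' specified by the config, writing rasters, CSV tables, and a log to
#' `output_dir`. Fully reproducible: rerunning with the same config and
#' seeds produces identical tables.
#'
#' @param config YAML path or config list (see [read_pipeline_config()]).
#' @param output_dir Overrides the config's `output_dir`.
#' @return Invisibly, a list with the fitted objects and artifact paths.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  cfg <- read_pipeline_config(config)
  out_dir <- output_dir %||% cfg$output_dir
  if (is.null(out_dir)) stop("config error: no output directory given")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  grid <- config_grid(cfg$grid)
  set.seed(cfg$seed)
  log_lines <- c(sprintf("resistmap pipeline: seed=%d", cfg$seed))

  # --- data ---------------------------------------------------------------
  if (!is.null(cfg$simulate)) {
    sim_args <- cfg$simulate
    sim_args$grid <- grid
    sim_args$seed <- cfg$seed
    scfg <- do.call(sim_config, sim_args)
    dat <- simulate_dataset(scfg)
    stack <- dat$stack
    bioassay <- dat$bioassay
    allele <- dat$allele
    write_observations(bioassay, file.path(out_dir, "bioassay.csv"))
    if (!is.null(allele))
      write_observations(allele, file.path(out_dir, "allele.csv"))
    log_lines <- c(log_lines, "data: synthetic")
  } else {
    bioassay <- read_observations(cfg$inputs$bioassay, "bioassay", grid)
    allele <- if (!is.null(cfg$inputs$allele))
      read_observations(cfg$inputs$allele, "allele", grid) else NULL
    stack <- read_covariate_stack(cfg$inputs$covariates, grid)
    log_lines <- c(log_lines, sprintf("data: %s", cfg$inputs$bioassay))
  }
  stack <- monthly_to_pcs(stack)

  # --- transforms + level-0 ------------------------------------------------
  tc <- cfg$transforms
  obs <- combine_labels(bioassay, allele, grid, tc$c)
  X <- assemble_features(obs, stack)
  group_levels <- attr(X, "group_levels")
  ens <- fit_ensemble(X, obs$label, specs = cfg$level0$specs,
                      K = cfg$level0$K, seed = derive_seed(cfg$seed, 21),
                      tune = isTRUE(cfg$level0$tune))
  imp_df <- data.frame(feature = rownames(ens$importances),
                       ens$importances, row.names = NULL)
  write.csv(imp_df, file.path(out_dir, "importances.csv"),
            row.names = FALSE)
  oof_df <- data.frame(obs_id = seq_len(nrow(X)),
                       fold = ens$fold_assignment, ens$oof_matrix,
                       row.names = NULL)
  write.csv(oof_df, file.path(out_dir, "oof_matrix.csv"), row.names = FALSE)
  for (p in names(ens$specs))
    log_lines <- c(log_lines, sprintf(
      "level0 %s: %s", p,
      paste(names(ens$specs[[p]]), unlist(ens$specs[[p]]), sep = "=",
            collapse = ",")))

  # --- meta-models per insecticide grouping --------------------------------
  nc <- n_cells(grid)
  ny <- length(grid$years)
  posteriors <- list()
  summaries <- NULL
  for (gname in names(cfg$stack$groups)) {
    rows <- obs$kind == "bioassay" &
      obs$insecticide %in% cfg$stack$groups[[gname]]
    if (!any(rows)) next
    fit <- fit_stack(obs$label[rows],
                     ens$oof_matrix[rows, , drop = FALSE],
                     obs$cell[rows], obs$year_idx[rows], grid,
                     n_draws = cfg$stack$n_draws,
                     seed = derive_seed(cfg$seed, 31))
    posteriors[[gname]] <- fit
    summaries <- rbind(summaries, cbind(group = gname, summary(fit)))
    log_lines <- c(log_lines, sprintf(
      "stack %s: sd=%.4f range=%.3f rho=%.4f sigma=%.4f", gname,
      fit$theta_map$sd, fit$theta_map$range_cells, fit$theta_map$rho,
      fit$theta_map$sigma))
  }
  write.csv(summaries, file.path(out_dir, "stack_parameters.csv"),
            row.names = FALSE)

  # --- prediction surfaces and summaries -----------------------------------
  pix <- data.frame(cell = rep(seq_len(nc), ny),
                    year_idx = rep(seq_len(ny), each = nc))
  pix$year <- grid$years[pix$year_idx]
  trends <- NULL
  surfaces <- list()
  for (ins in cfg$predict$insecticides) {
    gname <- if (ins == "DDT") "DDT" else "pyrethroids"
    if (is.null(posteriors[[gname]])) next
    pix$group <- observation_group("bioassay", ins, cfg$predict$protocol)
    Xp <- assemble_features(pix, stack, group_levels)
    M_pix <- vapply(ens$models, function(m) predict(m, Xp), numeric(nrow(Xp)))
    surf <- predict_stack(posteriors[[gname]], M_pix, c = tc$c,
                          n_ref = tc$n_ref)
    surfaces[[ins]] <- surf
    for (y in seq_len(ny)) {
      write_raster(surf$mean[, y], grid, file.path(
        out_dir, sprintf("mean_%s_%d.asc", ins, grid$years[y])))
      write_raster(surf$width[, y], grid, file.path(
        out_dir, sprintf("ciwidth_%s_%d.asc", ins, grid$years[y])))
    }
    tr <- area_below_threshold(surf, cfg$summaries$threshold)
    trends <- rbind(trends, cbind(insecticide = ins, tr))
    chg <- interannual_change(surf)
    write_raster(chg$max_increase, grid, file.path(
      out_dir, sprintf("max_increase_%s.asc", ins)))
    write_raster(chg$max_decrease, grid, file.path(
      out_dir, sprintf("max_decrease_%s.asc", ins)))
  }
  write.csv(trends, file.path(out_dir, "threshold_trends.csv"),
            row.names = FALSE)
  if (!is.null(posteriors$pyrethroids)) {
    wmeans <- colMeans(posteriors$pyrethroids$w_draws)
    wi <- weighted_importance(ens$importances, wmeans)
    write.csv(wi, file.path(out_dir, "weighted_importance.csv"),
              row.names = FALSE)
  }

  # --- optional cross-validation -------------------------------------------
  report <- NULL
  if (isTRUE(cfg$validate$enabled)) {
    report <- cross_validate(bioassay, allele, stack, grid,
                             K = cfg$validate$K,
                             seed = derive_seed(cfg$seed, 41),
                             specs = cfg$level0$specs,
                             n_draws = cfg$stack$n_draws, c = tc$c,
                             n_ref = tc$n_ref)
    rows <- NULL
    for (g in names(report$groups)) {
      gr <- report$groups[[g]]
      if (!isTRUE(gr$defined)) next
      rows <- rbind(rows, data.frame(
        group = g, n = gr$n, rmse_natural = gr$rmse_natural,
        mae_natural = gr$mae_natural,
        rmse_transformed = gr$rmse_transformed,
        coverage95 = gr$coverage[["0.95"]], pit_ks = gr$pit_hist$ks))
    }
    write.csv(rows, file.path(out_dir, "validation.csv"), row.names = FALSE)
  }

  writeLines(log_lines, file.path(out_dir, "log.txt"))
  yaml::write_yaml(cfg, file.path(out_dir, "config_used.yml"))
  invisible(list(config = cfg, grid = grid, stack = stack, obs = obs,
                 ensemble = ens, posteriors = posteriors,
                 surfaces = surfaces, trends = trends,
                 validation = report, output_dir = out_dir))
}

#' Write a synthetic dataset to disk in the pipeline's input formats
#'
#' @param cfg A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the dataset list from [simulate_dataset()].
#' @export
simulate_to_files <- function(cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dat <- simulate_dataset(cfg)
  write_observations(dat$bioassay, file.path(out_dir, "bioassay.csv"))
  if (!is.null(dat$allele))
    write_observations(dat$allele, file.path(out_dir, "allele.csv"))
  cov_dir <- file.path(out_dir, "covariates")
  dir.create(cov_dir, showWarnings = FALSE)
  st <- dat$stack
  for (l in seq_along(st$layer_names)) {
    for (y in seq_along(st$years)) {
      write_raster(st$layers[, y, l], cfg$grid, file.path(
        cov_dir, sprintf("%s_%d.asc", st$layer_names[l], st$years[y])))
    }
  }
  invisible(dat)
}
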