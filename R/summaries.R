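# Map summary statistics computed from prediction surfaces: threshold-area
# trends with credible intervals, per-country trends, maximum interannual
# change, and meta-model-weighted variable importance.

surface_parts <- function(surface) {
  if (inherits(surface, "prediction_surface")) {
    if (is.null(surface$draws))
      stop("prediction surface was built with keep_draws = FALSE")
    list(mean = surface$mean, draws = surface$draws, grid = surface$grid,
         years = surface$years)
  } else surface  # already a list(mean, draws, grid, years) toy table
}

#' Proportion of the area below a mortality threshold, by year
#'
#' For every year, the fraction of masked-in pixels whose predicted mean
#' mortality is below `threshold` (0.9 is the WHO threshold for confirmed
#' resistance). The point estimate uses the posterior mean surface; the 95%
#' credible interval is taken over per-draw proportions, so it reflects
#' joint spatial uncertainty.
#'
#' @param surface A `prediction_surface` (with draws) or a list with
#'   elements `mean` (`n_cells x n_years`), `draws`
#'   (`D x n_cells*n_years`), `grid`, `years`.
#' @param threshold Mortality threshold (default 0.9).
#' @param mask Optional logical vector over cells (row-major) replacing the
#'   grid mask (e.g. a country mask).
#' @param area_weight If `TRUE`, weight pixels by `cos(latitude)` instead
#'   of counting them equally.
#' @return Data frame with `year`, `proportion`, `lower`, `upper`.
#' @export
area_below_threshold <- function(surface, threshold = 0.9, mask = NULL,
                                 area_weight = FALSE) {
  sp <- surface_parts(surface)
  grid <- sp$grid
  nc <- n_cells(grid)
  ny <- length(sp$years)
  if (is.null(mask)) mask <- as.vector(t(grid$mask))
  if (is.matrix(mask)) mask <- as.vector(t(mask))
  if (!any(mask)) stop("empty mask")
  w <- if (area_weight) cos(cell_centers(grid)$lat * pi / 180) else rep(1, nc)
  w <- w[mask]
  frac <- function(x) sum(w * (x[mask] < threshold)) / sum(w)
  out <- data.frame(year = sp$years, proportion = NA_real_,
                    lower = NA_real_, upper = NA_real_)
  for (y in seq_len(ny)) {
    idx <- (y - 1) * nc + seq_len(nc)
    per_draw <- apply(sp$draws[, idx, drop = FALSE], 1, frac)
    out$proportion[y] <- frac(sp$mean[, y])
    out$lower[y] <- quantile(per_draw, 0.025, names = FALSE)
    out$upper[y] <- quantile(per_draw, 0.975, names = FALSE)
  }
  out
}

#' Threshold-area trends per country
#'
#' Applies [area_below_threshold()] to each country mask; countries with no
#' unmasked pixels are skipped with a warning.
#'
#' @param surface See [area_below_threshold()].
#' @param country_masks Named list of logical cell masks (each a subset of
#'   the region mask).
#' @param threshold,area_weight Passed through.
#' @return Data frame with a `country` column prepended.
#' @export
country_trends <- function(surface, country_masks, threshold = 0.9,
                           area_weight = FALSE) {
  out <- NULL
  for (cn in names(country_masks)) {
    m <- country_masks[[cn]]
    if (is.matrix(m)) m <- as.vector(t(m))
    if (!any(m)) {
      warning("country ", cn, " has zero unmasked pixels; skipped")
      next
    }
    tr <- area_below_threshold(surface, threshold, mask = m,
                               area_weight = area_weight)
    out <- rbind(out, cbind(country = cn, tr))
  }
  out
}

#' Maximum interannual change in predicted mortality
#'
#' Per pixel, the maximum over consecutive-year pairs of the year-on-year
#' increase (`next - current`) and of the decrease (`current - next`) in
#' predicted mean mortality. A decline in mortality corresponds to a rise
#' in resistance.
#'
#' @param mean_surface `n_cells x n_years` matrix of mean mortality (or a
#'   `prediction_surface`, whose `mean` is used).
#' @return List with per-pixel vectors `max_increase` and `max_decrease`.
#' @export
interannual_change <- function(mean_surface) {
  m <- if (inherits(mean_surface, "prediction_surface")) mean_surface$mean
       else as.matrix(mean_surface)
  if (ncol(m) < 2) stop("need at least 2 years")
  d <- m[, -1, drop = FALSE] - m[, -ncol(m), drop = FALSE]
  list(max_increase = apply(d, 1, max),
       max_decrease = apply(-d, 1, max))
}

#' Variable importance weighted by meta-model weights
#'
#' Multiplies each level-0 model's normalised importance vector by the
#' posterior mean weight of that model in the meta-model and ranks features
#' by the summed weighted importance across models (the height of the
#' stacked bars).
#'
#' @param importances `n_features x n_models` matrix (feature names as row
#'   names) or a named list of per-model importance vectors sharing one
#'   feature index, each summing to 1.
#' @param weights Named nonnegative weights, one per model (posterior
#'   means).
#' @param top_n Number of top-ranked features to return (default all).
#' @return Data frame ordered by decreasing total weighted importance, with
#'   per-model weighted components and the `total`.
#' @export
weighted_importance <- function(importances, weights, top_n = NULL) {
  if (is.list(importances)) {
    feats <- lapply(importances, names)
    all_f <- Reduce(union, feats)
    shared <- Reduce(intersect, feats)
    if (length(setdiff(all_f, shared)))
      stop("mismatched feature sets: ",
           paste(setdiff(all_f, shared), collapse = ", "))
    importances <- vapply(importances, function(v) v[all_f],
                          numeric(length(all_f)))
    rownames(importances) <- all_f
  }
  importances <- as.matrix(importances)
  if (is.null(names(weights))) names(weights) <- colnames(importances)
  extra <- union(setdiff(colnames(importances), names(weights)),
                 setdiff(names(weights), colnames(importances)))
  if (length(extra))
    stop("mismatched model sets: ", paste(extra, collapse = ", "))
  stopifnot(all(weights >= 0))
  W <- sweep(importances[, names(weights), drop = FALSE], 2, weights, `*`)
  total <- rowSums(W)
  out <- data.frame(feature = rownames(importances), W, total = total,
                    row.names = NULL, check.names = FALSE)
  out <- out[order(-out$total), ]
  if (!is.null(top_n)) out <- head(out, top_n)
  out
}
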