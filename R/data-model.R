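#' @useDynLib resistmap, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optim optimHess pnorm qnorm quantile rbinom rnorm runif
#'   sd var rnbinom rchisq prcomp predict coef lm lm.fit uniroot setNames cor
#' @importFrom utils write.csv read.csv head
NULL

INSECTICIDES <- c("deltamethrin", "permethrin", "lambda_cyhalothrin",
                  "alpha_cypermethrin", "DDT")
PYRETHROIDS <- setdiff(INSECTICIDES, "DDT")
PROTOCOLS <- c("WHO", "CDC")

#' Define a regular lat/long prediction grid
#'
#' Grid cells are addressed row-major from the north-west corner; a pixel
#' value refers to the cell centre. The default cell size of 1/24 degree
#' (2.5 arc-minutes) matches the resolution used for resistance mapping.
#'
#' @param origin_lon,origin_lat Coordinates of the north-west corner of the
#'   grid (the outer corner of cell `[1, 1]`), in decimal degrees.
#' @param cellsize Cell edge length in degrees; default `1/24`.
#' @param n_cols,n_rows Grid dimensions.
#' @param mask Logical matrix (`n_rows x n_cols`) of cells inside the region
#'   of interest; default all `TRUE`.
#' @param years Ordered integer vector of modelled years.
#' @return An object of class `grid_definition`.
#' @export
grid_definition <- function(origin_lon, origin_lat, cellsize = 1 / 24,
                            n_cols, n_rows, mask = NULL,
                            years = 2005:2017) {
  stopifnot(cellsize > 0, n_cols >= 1, n_rows >= 1,
            is.finite(origin_lon), is.finite(origin_lat))
  if (is.null(mask)) mask <- matrix(TRUE, n_rows, n_cols)
  if (!is.matrix(mask) || nrow(mask) != n_rows || ncol(mask) != n_cols)
    stop("`mask` must be a logical matrix with n_rows x n_cols entries")
  stopifnot(!is.unsorted(years))
  structure(list(origin_lon = origin_lon, origin_lat = origin_lat,
                 cellsize = cellsize, n_cols = n_cols, n_rows = n_rows,
                 mask = mask, years = as.integer(years)),
            class = "grid_definition")
}

#' @export
print.grid_definition <- function(x, ...) {
  cat(sprintf("grid_definition: %d x %d cells of %.6g deg, NW corner (%.4g, %.4g)\n",
              x$n_rows, x$n_cols, x$cellsize, x$origin_lon, x$origin_lat))
  cat(sprintf("  years %d-%d; %d of %d cells inside mask\n",
              min(x$years), max(x$years), sum(x$mask), length(x$mask)))
  invisible(x)
}

n_cells <- function(grid) grid$n_rows * grid$n_cols

#' Cell-centre coordinates of every grid cell
#'
#' @param grid A [grid_definition()].
#' @return Data frame with `cell`, `row`, `col`, `lon`, `lat`, `inside`
#'   (mask flag), one row per cell in row-major order from the NW corner.
#' @export
cell_centers <- function(grid) {
  row <- rep(seq_len(grid$n_rows), each = grid$n_cols)
  col <- rep(seq_len(grid$n_cols), times = grid$n_rows)
  data.frame(
    cell = seq_len(n_cells(grid)),
    row = row, col = col,
    lon = grid$origin_lon + (col - 0.5) * grid$cellsize,
    lat = grid$origin_lat - (row - 0.5) * grid$cellsize,
    inside = as.vector(t(grid$mask)))
}

#' Snap point coordinates to their containing grid cell
#'
#' Observations keep exact coordinates in the data model; snapping is used
#' only to evaluate the latent field and covariates at the containing pixel.
#'
#' @param grid A [grid_definition()].
#' @param lon,lat Point coordinates in degrees.
#' @return Integer vector of row-major cell indices (`NA` outside the grid).
#' @export
point_to_cell <- function(grid, lon, lat) {
  col <- floor((lon - grid$origin_lon) / grid$cellsize) + 1
  row <- floor((grid$origin_lat - lat) / grid$cellsize) + 1
  ok <- col >= 1 & col <= grid$n_cols & row >= 1 & row <= grid$n_rows
  out <- ifelse(ok, (row - 1) * grid$n_cols + col, NA_integer_)
  as.integer(out)
}

bioassay_columns <- c("site_id", "lon", "lat", "year", "insecticide",
                      "protocol", "n_tested", "mortality")
allele_columns <- c("site_id", "lon", "lat", "year", "frequency", "n_alleles")

validate_observations <- function(df, schema = c("bioassay", "allele"),
                                  grid = NULL) {
  schema <- match.arg(schema)
  need <- if (schema == "bioassay") bioassay_columns else allele_columns
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("schema error: missing column(s) ", paste(missing_cols, collapse = ", "))
  bad <- function(cond, what) {
    rows <- which(cond)
    if (length(rows))
      stop(sprintf("validation error: %s in row(s) %s", what,
                   paste(rows, collapse = ", ")))
  }
  bad(!is.finite(df$lon) | !is.finite(df$lat), "non-finite coordinates")
  if (schema == "bioassay") {
    bad(df$mortality < 0 | df$mortality > 1, "mortality outside [0,1]")
    bad(df$n_tested < 1, "n_tested < 1")
    bad(!df$insecticide %in% INSECTICIDES, "unknown insecticide")
    bad(!df$protocol %in% PROTOCOLS, "unknown protocol")
  } else {
    bad(df$frequency < 0 | df$frequency > 1, "frequency outside [0,1]")
    bad(df$n_alleles < 1, "n_alleles < 1")
  }
  if (!is.null(grid)) {
    cell <- point_to_cell(grid, df$lon, df$lat)
    inside <- !is.na(cell) & as.vector(t(grid$mask))[cell]
    bad(!inside, "coordinates outside the region mask")
  }
  df
}

#' Read validated observation tables
#'
#' Reads a delimited text file of bioassay mortality or *Vgsc*
#' allele-frequency observations, checks the documented schema, and rejects
#' rows that violate the data-model invariants with row-indexed diagnostics.
#'
#' @param path CSV file path. Bioassay schema columns: `site_id, lon, lat,
#'   year, insecticide, protocol, n_tested, mortality`; allele schema:
#'   `site_id, lon, lat, year, frequency, n_alleles`.
#' @param schema `"bioassay"` or `"allele"`.
#' @param grid Optional [grid_definition()]; when supplied, observations
#'   outside the region mask are rejected.
#' @return A validated `data.frame`.
#' @export
read_observations <- function(path, schema = c("bioassay", "allele"),
                              grid = NULL) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- as.data.frame(data.table::fread(path))
  validate_observations(df, schema, grid)
}

#' Write an observation table
#'
#' @param df Observation data frame (bioassay or allele schema).
#' @param path Output CSV path.
#' @export
write_observations <- function(df, path) {
  data.table::fwrite(df, path)
  invisible(path)
}

#' Write a single-band georeferenced text raster (ESRI ASCII grid)
#'
#' Writes per-pixel values on a [grid_definition()] to the standard ESRI
#' ASCII grid format (readable by GDAL and most GIS software). Cells outside
#' the mask, and non-finite values, are written as the no-data value. Finite
#' values round-trip bit-exactly through [read_raster()].
#'
#' @param values Numeric vector of length `n_rows * n_cols` (row-major from
#'   the NW corner) or a matrix of matching shape.
#' @param grid A [grid_definition()].
#' @param path Output path (conventionally `.asc`).
#' @param nodata No-data sentinel written for masked cells.
#' @export
write_raster <- function(values, grid, path, nodata = -9999) {
  if (is.matrix(values)) {
    if (nrow(values) != grid$n_rows || ncol(values) != grid$n_cols)
      stop("dimension error: values matrix does not match grid shape")
    values <- as.vector(t(values))
  }
  if (length(values) != n_cells(grid))
    stop("dimension error: expected ", n_cells(grid), " values, got ",
         length(values))
  mask <- as.vector(t(grid$mask))
  v <- values
  v[!mask | !is.finite(v)] <- nodata
  header <- c(
    sprintf("ncols %d", grid$n_cols),
    sprintf("nrows %d", grid$n_rows),
    sprintf("xllcorner %.10f", grid$origin_lon),
    sprintf("yllcorner %.10f", grid$origin_lat - grid$n_rows * grid$cellsize),
    sprintf("cellsize %.12f", grid$cellsize),
    sprintf("NODATA_value %g", nodata))
  rows <- vapply(seq_len(grid$n_rows), function(r) {
    paste(sprintf("%.17g", v[((r - 1) * grid$n_cols + 1):(r * grid$n_cols)]),
          collapse = " ")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read an ESRI ASCII grid raster
#'
#' @param path File written by [write_raster()] (or any ESRI ASCII grid).
#' @return List with `values` (row-major vector, `NA` at no-data cells),
#'   `n_cols`, `n_rows`, `xllcorner`, `yllcorner`, `cellsize`, `nodata`.
#' @export
read_raster <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  keys <- tolower(vapply(hdr, `[`, character(1), 1))
  vals <- as.numeric(vapply(hdr, `[`, character(1), 2))
  names(vals) <- keys
  values <- scan(text = paste(lines[-(1:6)], collapse = " "), quiet = TRUE)
  values[values == vals[["nodata_value"]]] <- NA_real_
  list(values = values, n_cols = as.integer(vals[["ncols"]]),
       n_rows = as.integer(vals[["nrows"]]), xllcorner = vals[["xllcorner"]],
       yllcorner = vals[["yllcorner"]], cellsize = vals[["cellsize"]],
       nodata = vals[["nodata_value"]])
}

#' Observation group labels
#'
#' Every observation belongs to exactly one group formed from the observation
#' kind, the insecticide, and the test protocol; allele-frequency
#' observations form their own single group. The group enters the level-0
#' learners as a factor feature.
#'
#' @param kind `"bioassay"` or `"allele"`, recycled.
#' @param insecticide,protocol Bioassay attributes (ignored for alleles).
#' @return Character vector of group ids.
#' @export
observation_group <- function(kind, insecticide = NA, protocol = NA) {
  ifelse(kind == "allele", "allele",
         paste("bioassay", insecticide, protocol, sep = "."))
}
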