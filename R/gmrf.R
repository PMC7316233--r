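# Separable spatiotemporal Gaussian Markov random field on the prediction
# grid: a Matern-like (SPDE, alpha = 2) sparse spatial precision on the
# lattice graph crossed with a stationary AR(1) precision across years.
# Spatial precision is empirically normalised to unit marginal variance so
# `field_sd` is interpretable as the marginal standard deviation.

lattice_laplacian <- function(n_rows, n_cols) {
  n <- n_rows * n_cols
  idx <- matrix(seq_len(n), nrow = n_rows, ncol = n_cols, byrow = TRUE)
  i <- c(); j <- c()
  if (n_cols > 1) {
    a <- as.vector(idx[, -n_cols]); b <- as.vector(idx[, -1])
    i <- c(i, a, b); j <- c(j, b, a)
  }
  if (n_rows > 1) {
    a <- as.vector(idx[-n_rows, ]); b <- as.vector(idx[-1, ])
    i <- c(i, a, b); j <- c(j, b, a)
  }
  W <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
  Matrix::Diagonal(n, Matrix::rowSums(W)) - W
}

#' Spatial lattice precision with unit marginal variance
#'
#' Builds the sparse SPDE-type (alpha = 2) precision `(kappa^2 I + L)^2` on
#' the grid graph, with `kappa = sqrt(8) / range` (range in cell units), and
#' rescales it so the average marginal variance equals 1.
#'
#' @param n_rows,n_cols Lattice dimensions.
#' @param range_cells Spatial correlation range, in cell units.
#' @return Sparse symmetric positive-definite precision matrix.
#' @keywords internal
spatial_precision <- function(n_rows, n_cols, range_cells) {
  stopifnot(range_cells > 0)
  n <- n_rows * n_cols
  kappa <- sqrt(8) / range_cells
  L <- lattice_laplacian(n_rows, n_cols)
  B <- kappa^2 * Matrix::Diagonal(n) + L
  Q <- Matrix::forceSymmetric(B %*% B)
  # empirical normalisation: scale so mean marginal variance is 1
  R <- chol(as.matrix(Q))
  mv <- mean(diag(chol2inv(R)))
  out <- Matrix::forceSymmetric(Q * mv)
  attr(out, "ldet") <- 2 * sum(log(diag(R))) + n * log(mv)
  out
}

#' Stationary AR(1) precision with unit marginal variance
#' @keywords internal
ar1_precision <- function(n, rho) {
  stopifnot(abs(rho) < 1)
  if (n == 1) return(Matrix::Diagonal(1))
  d <- c(1, rep(1 + rho^2, n - 2), 1)
  Q <- Matrix::bandSparse(n, k = c(0, 1), symmetric = TRUE,
                          diagonals = list(d, rep(-rho, n - 1)))
  Matrix::forceSymmetric(Q / (1 - rho^2))
}

#' Separable space-time GMRF precision
#'
#' Index order is `(year - 1) * n_cells + cell` (cells row-major from the NW
#' corner), i.e. `kron(Q_time, Q_space)`.
#'
#' @param n_rows,n_cols Lattice dimensions.
#' @param n_years Number of years.
#' @param field_sd Marginal standard deviation of the field.
#' @param range_cells Spatial range in cell units.
#' @param rho AR(1) correlation across years, `|rho| < 1`.
#' @return Sparse precision of dimension `n_rows*n_cols*n_years`.
#' @keywords internal
st_precision <- function(n_rows, n_cols, n_years, field_sd, range_cells,
                         rho) {
  stopifnot(field_sd > 0)
  Qs <- spatial_precision(n_rows, n_cols, range_cells)
  Qt <- ar1_precision(n_years, rho)
  Matrix::forceSymmetric(Matrix::kronecker(Qt, Qs) / field_sd^2)
}

# Draws from N(0, Q^-1) via the permuted sparse Cholesky Q = P' L L' P:
# solve L' v = z then un-permute.
sample_gmrf <- function(Q, n_draws = 1) {
  ch <- Matrix::Cholesky(Q, LDL = FALSE, perm = TRUE)
  z <- matrix(rnorm(nrow(Q) * n_draws), nrow(Q), n_draws)
  v <- Matrix::solve(ch, z, system = "Lt")
  as.matrix(Matrix::solve(ch, v, system = "Pt"))
}
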