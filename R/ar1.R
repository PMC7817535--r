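## Separable AR1 x AR1 correlation structures.

#' AR1 correlation matrix
#'
#' `C[i, j] = rho^|i - j|` for a sequence of `n` equally spaced positions.
#'
#' @param n dimension (>= 1).
#' @param rho autocorrelation, `|rho| < 1`.
#' @return an `n x n` symmetric positive-definite matrix.
#' @export
ar1_corr <- function(n, rho) {
  stopifnot_scalar_count(n, "n")
  if (!is.numeric(rho) || abs(rho) >= 1)
    stop("`rho` must satisfy |rho| < 1", call. = FALSE)
  rho^abs(outer(seq_len(n), seq_len(n), "-"))
}

#' Simulate a separable AR1 x AR1 Gaussian field
#'
#' Draws one realisation of a zero-mean Gaussian field on an
#' `n_rows x n_cols` grid with covariance
#' `sigma2 * rho_row^|dr| * rho_col^|dc|`, exactly, via the Kronecker
#' structure: `F = sqrt(sigma2) * L_r Z L_c'` with `L` lower Cholesky
#' factors of the two AR1 correlation matrices and `Z` iid standard normal.
#'
#' @param n_rows,n_cols grid dimensions.
#' @param rho_row,rho_col autocorrelations along rows and columns.
#' @param sigma2 marginal variance.
#' @param seed optional integer seed (uses the current RNG stream if `NULL`).
#' @return an `n_rows x n_cols` matrix.
#' @export
simulate_ar1_field <- function(n_rows, n_cols, rho_row, rho_col, sigma2,
                               seed = NULL) {
  if (sigma2 < 0) stop("`sigma2` must be >= 0", call. = FALSE)
  if (sigma2 == 0) return(matrix(0, n_rows, n_cols))
  draw <- function() {
    z <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
    lr <- t(chol(ar1_corr(n_rows, rho_row)))
    lc <- t(chol(ar1_corr(n_cols, rho_col)))
    sqrt(sigma2) * lr %*% z %*% t(lc)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Residual covariance of observed grid cells
#'
#' The AR1 x AR1 plus nugget residual covariance for the observed cells of a
#' complete rectangular grid:
#' `R = sigma2_xi * (C_row(rho_row) (x) C_col(rho_col))[obs, obs] +
#'  sigma2_eta * I`. Missing cells enter only through the restriction of the
#' index set; distances are in grid steps.
#'
#' @param rows,cols integer grid indices of the observed cells (equal
#'   length; each `(row, col)` pair unique).
#' @param sigma2_xi spatially correlated variance.
#' @param rho_row,rho_col AR1 autocorrelations, `|rho| < 1`.
#' @param sigma2_eta independent (nugget / units) variance.
#' @return a dense covariance matrix over the observations.
#' @export
residual_cov <- function(rows, cols, sigma2_xi, rho_row, rho_col,
                         sigma2_eta = 0) {
  if (length(rows) != length(cols))
    stop("`rows` and `cols` must have equal length", call. = FALSE)
  if (anyDuplicated(cbind(rows, cols)))
    stop("duplicate (row, col) grid cells", call. = FALSE)
  if (abs(rho_row) >= 1 || abs(rho_col) >= 1)
    stop("|rho| must be < 1", call. = FALSE)
  if (sigma2_xi < 0 || sigma2_eta < 0)
    stop("variances must be >= 0", call. = FALSE)
  n <- length(rows)
  R <- sigma2_xi *
    rho_row^abs(outer(rows, rows, "-")) *
    rho_col^abs(outer(cols, cols, "-"))
  R + diag(rep(sigma2_eta, n))
}
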