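#' Rank-1 EM imputation of a log-measurement matrix
#'
#' Completes missing cells of a specimens x dimensions matrix of
#' natural-log measurements by iterative rank-1 EM: missing cells are
#' initialised at column means; each iteration recentres the columns, takes
#' the leading singular component of the centred matrix, and replaces the
#' missing cells by the rank-1 reconstruction; iteration stops when the
#' largest absolute update of any imputed cell falls below `tol` or after
#' `max_iter` iterations.  Present cells are never altered.
#'
#' Growth data of a single taxon are dominated by a common latent size axis,
#' so the centred log matrix is close to rank 1; on exactly rank-1 data with
#' deleted cells the fixed point of this scheme is the unique rank-1
#' completion.
#'
#' @param x Numeric matrix (specimens x dimensions) of log measurements with
#'   `NA` for missing cells.  Every row and every column must contain at
#'   least one present cell, and at least 3 rows are required.
#' @param tol Convergence threshold on the max absolute log-scale update.
#' @param max_iter Maximum number of EM iterations.  Non-convergence is
#'   reported, not an error.
#' @return A list with components `x` (the completed matrix) and `report`, a
#'   list with `cells_imputed`, `iterations`, `converged` and `final_change`.
#' @export
impute_log_missing <- function(x, tol = 1e-8, max_iter = 500L) {
  stopifnot(is.matrix(x), is.numeric(x))
  if (nrow(x) < 3L) stop("need at least 3 specimens (rows)")
  miss <- is.na(x)
  if (any(rowSums(!miss) == 0L)) stop("row with no present cells")
  if (any(colSums(!miss) == 0L)) stop("column with no present cells")
  n_miss <- sum(miss)
  if (n_miss == 0L) {
    return(list(x = x,
                report = list(cells_imputed = 0L, iterations = 0L,
                              converged = TRUE, final_change = 0)))
  }
  # init at column means of present cells
  mu <- colMeans(x, na.rm = TRUE)
  xf <- x
  xf[miss] <- mu[col(x)][miss]
  change <- Inf
  iter <- 0L
  while (iter < max_iter && change >= tol) {
    iter <- iter + 1L
    mu <- colMeans(xf)
    xc <- sweep(xf, 2L, mu)
    sv <- svd(xc, nu = 1L, nv = 1L)
    recon <- sv$d[1L] * tcrossprod(sv$u[, 1L], sv$v[, 1L])
    new_vals <- sweep(recon, 2L, mu, `+`)[miss]
    change <- max(abs(new_vals - xf[miss]))
    xf[miss] <- new_vals
  }
  list(x = xf,
       report = list(cells_imputed = n_miss,
                     iterations = iter,
                     converged = change < tol,
                     final_change = change))
}
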