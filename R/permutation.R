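#' Paired sign-flip permutation (symmetry) test
#'
#' Two-sided test of the symmetry of paired differences about zero, the
#' permutation analogue of a paired t test.  The statistic is the mean
#' paired difference `T = mean(x - y)`; the null distribution is generated
#' by independently flipping the sign of each difference.  With `n <= 20`
#' pairs (or `mode = "exact"`) all `2^n` sign patterns are enumerated and
#' the two-sided p-value is the exact proportion of patterns with
#' `|T*| >= |T|` (the observed arrangement is one of them, so p > 0).
#' Otherwise `n_perm` random sign patterns are drawn and the add-one
#' (permutation-inclusive) estimate `(1 + #{|T*| >= |T|}) / (n_perm + 1)`
#' is returned.
#'
#' Pairing is positional: the two series must be observed on the same
#' wingspan grid (no interpolation is attempted).
#'
#' @param x,y Numeric vectors of equal length `n >= 2` (e.g. an index along
#'   two taxa's shared wingspan grid).
#' @param mode `"auto"` (exact when `n <= 20`), `"exact"`, or
#'   `"montecarlo"`.
#' @param n_perm Monte-Carlo sample size (default 1e5).
#' @param seed Integer seed used in Monte-Carlo mode; recorded.
#' @return Object of classes `perm_test` and `htest`, with fields
#'   `statistic` (mean difference), `p.value`, `mode`, `n_permutations`,
#'   `seed`, and `degenerate` (`TRUE` when all differences are zero, in
#'   which case p = 1).
#' @export
#' @examples
#' paired_permutation_test(c(1, 2, 4), c(0, 0, 1))
paired_permutation_test <- function(x, y,
                                    mode = c("auto", "exact", "montecarlo"),
                                    n_perm = 1e5L, seed = 1L) {
  mode <- match.arg(mode)
  if (length(x) != length(y))
    stop("x and y must be paired series of equal length (same grid)")
  n <- length(x)
  if (n < 2L) stop("need at least 2 pairs")
  d <- x - y
  t_obs <- mean(d)
  degenerate <- all(d == 0)
  if (mode == "auto") mode <- if (n <= 20L) "exact" else "montecarlo"
  if (degenerate) {
    p <- 1
    n_used <- 0L
  } else if (mode == "exact") {
    if (n > 25L) stop("exact enumeration limited to n <= 25 pairs")
    tol <- 1e-12 * max(abs(d))
    total <- 0
    hits <- 0
    chunk <- 2^min(n, 16L)
    blocks <- 2^(n - min(n, 16L))
    low <- as.matrix(expand.grid(rep(list(c(-1, 1)), min(n, 16L))))
    for (b in seq_len(blocks)) {
      if (blocks > 1L) {
        hi_bits <- as.integer(intToBits(b - 1L))[seq_len(n - 16L)]
        hi <- ifelse(hi_bits == 1L, 1, -1)
        signs <- cbind(low, matrix(hi, nrow = chunk, ncol = n - 16L,
                                   byrow = TRUE))
      } else {
        signs <- low
      }
      t_star <- as.vector(signs %*% d) / n
      hits <- hits + sum(abs(t_star) >= abs(t_obs) - tol)
      total <- total + nrow(signs)
    }
    p <- hits / total
    n_used <- total
  } else {
    set.seed(seed)
    signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                    nrow = n_perm)
    t_star <- as.vector(signs %*% d) / n
    tol <- 1e-12 * max(abs(d))
    p <- (1 + sum(abs(t_star) >= abs(t_obs) - tol)) / (n_perm + 1)
    n_used <- as.integer(n_perm)
  }
  structure(list(statistic = c(`mean difference` = t_obs),
                 p.value = p,
                 parameter = c(n = n),
                 method = sprintf("Paired sign-flip permutation test (%s)",
                                  mode),
                 data.name = paste(deparse(substitute(x)), "vs",
                                   deparse(substitute(y))),
                 alternative = "two.sided",
                 mode = mode, n_permutations = n_used, seed = seed,
                 degenerate = degenerate),
            class = c("perm_test", "htest"))
}

#' Pairwise permutation comparison of taxa performance series
#'
#' Runs [paired_permutation_test()] on one flight-performance index for
#' every pair of taxa, pairing values at identical wingspan grid points.
#'
#' @param series_list Named list of `flight_performance` data frames (one
#'   per taxon) sharing a wingspan grid.
#' @param index Column to compare: `"cot_inv"` or `"glide_ratio"`.
#' @param alpha Significance level for the significance mask (default 0.05).
#' @param ... Passed to [paired_permutation_test()].
#' @return List with `p_values` (symmetric matrix), `significant` (logical
#'   matrix, `p < alpha`), `index`, `alpha`.
#' @export
pairwise_performance_tests <- function(series_list,
                                       index = c("cot_inv", "glide_ratio"),
                                       alpha = 0.05, ...) {
  index <- match.arg(index)
  k <- length(series_list)
  if (k < 2L) stop("need at least two taxa to compare")
  nms <- names(series_list)
  grids <- lapply(series_list, function(s) round(s$wingspan_m, 9))
  base_grid <- Reduce(intersect, grids)
  if (!length(base_grid)) stop("taxa share no wingspan grid points")
  pm <- matrix(NA_real_, k, k, dimnames = list(nms, nms))
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      xi <- series_list[[i]][[index]][match(base_grid, grids[[i]])]
      yj <- series_list[[j]][[index]][match(base_grid, grids[[j]])]
      pt <- paired_permutation_test(xi, yj, ...)
      pm[i, j] <- pm[j, i] <- pt$p.value
    }
  }
  diag(pm) <- 1
  list(p_values = pm, significant = pm < alpha, index = index, alpha = alpha)
}
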