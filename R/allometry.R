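#' Multivariate growth allometry from a specimen table
#'
#' Fits the multivariate (principal-component) model of growth allometry to a
#' table of log skeletal measurements.  Specimens of one taxon are assumed to
#' lie, up to log-normal scatter, on a single power-law growth trajectory;
#' the first eigenvector of the covariance matrix of the natural-log
#' measurements is the direction of joint growth, and rescaling it by
#' `sqrt(p)` (Jolicoeur's convention, `p` = number of dimensions) gives one
#' allometric coefficient (AC) per dimension, equal to 1 under isometry,
#' above 1 for positive and below 1 for negative allometry.
#'
#' Missing cells (ubiquitous in fossil material) are first completed by
#' rank-1 EM imputation ([impute_log_missing()]); a complete-case analysis
#' would discard most specimens of fragmentary taxa.  One-tailed 95%
#' bootstrap bounds are then attached to each AC by resampling specimens
#' (rows of the completed log matrix) with replacement: for a point AC below
#' 1 the 95th percentile is reported as an upper bound, otherwise the 5th
#' percentile as a lower bound (percentile method, type-7 interpolation).
#' Each dimension is classified `"-"` (negative allometry) when an upper
#' bound lies below 1, `"+"` (positive) when a lower bound lies above 1, and
#' `"="` (isometry) otherwise; see [classify_allometry()].
#'
#' @param x A [specimen_table].
#' @param dims Dimensions to analyse (ordered subset of
#'   [dimension_vocabulary()]).  Default: every vocabulary dimension present
#'   in the table with at least one measurement.  Wingspan should be included
#'   whenever the fit will seed growth extrapolation, so that the wingspan
#'   coefficient comes from the same eigenvector.
#' @param combine_wp34 Treat WP3 + WP4 as a single dimension `wp34`
#'   (combined length), the anurognathid convention.
#' @param boot Number of bootstrap replicates (`B`).  `0` disables the
#'   bootstrap (bounds and classes are then `NA`).
#' @param seed Integer seed for the bootstrap, recorded in the result.
#' @param alpha One-tailed bound level (default 0.05, i.e. 95% bounds).
#' @param normalization `"sqrtp"` for Jolicoeur's `u * sqrt(p)` (default) or
#'   `"sump"` for `p * u / sum(u)`; both equal 1 elementwise under isometry.
#' @param tol,max_iter Passed to [impute_log_missing()].
#' @return An object of class `allometry`; see Details.  Its `table`
#'   component has one row per dimension with columns `dimension`, `ac`,
#'   `bound`, `side` and `class`.
#' @seealso [predict.allometry()] for growth extrapolation,
#'   [simulate.allometry()] for generating synthetic tables from the fit.
#' @export
#' @examples
#' cfg <- preset_library()[["Rhamphorhynchus"]]
#' tab <- generate_taxon(cfg)
#' fit <- allometry(tab, boot = 200, seed = 1)
#' fit
#' coef(fit)
allometry <- function(x, dims = NULL, combine_wp34 = FALSE,
                      boot = 1000L, seed = 1L, alpha = 0.05,
                      normalization = c("sqrtp", "sump"),
                      tol = 1e-8, max_iter = 500L) {
  stopifnot(inherits(x, "specimen_table"))
  normalization <- match.arg(normalization)
  cl <- match.call()

  m <- as.data.frame(x[, setdiff(names(x), "specimen_id"), drop = FALSE])
  if (combine_wp34) {
    if (!all(c("wp3", "wp4") %in% names(m)))
      stop("combine_wp34 requires both wp3 and wp4 columns")
    m$wp34 <- m$wp3 + m$wp4          # NA if either phalanx is missing
    m$wp3 <- NULL
    m$wp4 <- NULL
  }
  if (is.null(dims)) {
    dims <- names(m)[colSums(!is.na(m)) > 0L]
  } else {
    dims <- as.character(dims)
    if (combine_wp34 && any(c("wp3", "wp4") %in% dims))
      stop("with combine_wp34, use 'wp34' instead of wp3/wp4 in 'dims'")
    missing_dims <- setdiff(dims, names(m))
    if (length(missing_dims))
      stop("dimension(s) not in table: ", paste(missing_dims, collapse = ", "))
  }
  m <- m[dims]
  usable <- rowSums(!is.na(m)) > 0L
  m <- m[usable, , drop = FALSE]
  n <- nrow(m)
  p <- ncol(m)
  if (n < 3L) stop("fewer than 3 usable specimens")
  empty <- dims[colSums(!is.na(m)) == 0L]
  if (length(empty))
    stop("dimension(s) with no data: ", paste(empty, collapse = ", "))

  lx <- log(as.matrix(m))
  imp <- impute_log_missing(lx, tol = tol, max_iter = max_iter)
  xc <- imp$x

  novar <- dims[apply(xc, 2L, stats::var) < 1e-12]
  if (length(novar))
    stop("zero-variance dimension(s): ", paste(novar, collapse = ", "))

  est <- .allometry_coefs(xc, normalization)

  bounds <- rep(NA_real_, p)
  side <- rep(NA_character_, p)
  klass <- rep(NA_character_, p)
  discarded <- 0L
  if (boot > 0L) {
    set.seed(seed)
    reps <- matrix(NA_real_, nrow = boot, ncol = p)
    kept <- 0L
    tries <- 0L
    while (kept < boot) {
      tries <- tries + 1L
      idx <- sample.int(n, n, replace = TRUE)
      xb <- xc[idx, , drop = FALSE]
      if (any(apply(xb, 2L, stats::var) < 1e-12)) {
        discarded <- discarded + 1L
        if (discarded > 0.1 * boot)
          stop("more than 10% of bootstrap resamples were degenerate")
        next
      }
      kept <- kept + 1L
      reps[kept, ] <- .allometry_coefs(xb, normalization)$ac
    }
    for (j in seq_len(p)) {
      if (est$ac[j] < 1) {
        side[j] <- "upper"
        bounds[j] <- stats::quantile(reps[, j], 1 - alpha,
                                     names = FALSE, type = 7)
      } else {
        side[j] <- "lower"
        bounds[j] <- stats::quantile(reps[, j], alpha,
                                     names = FALSE, type = 7)
      }
    }
    klass <- classify_allometry(est$ac, bounds, side)
  }

  tab <- data.frame(dimension = dims, ac = est$ac, bound = bounds,
                    side = side, class = klass,
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(taxon = attr(x, "taxon"), table = tab,
                 p_used = p, n_used = n, B = boot, seed = seed,
                 alpha = alpha, normalization = normalization,
                 eigenvalues = est$values, loadings = est$u,
                 center = colMeans(xc), completed_log = xc,
                 imputation = imp$report,
                 bootstrap_discarded = discarded, call = cl),
            class = "allometry")
}

# Leading-eigenvector allometric coefficients of a completed log matrix.
.allometry_coefs <- function(xc, normalization = "sqrtp") {
  cv <- stats::cov(xc)
  e <- eigen(cv, symmetric = TRUE)
  u <- e$vectors[, 1L]
  if (mean(u) < 0) u <- -u
  p <- ncol(xc)
  ac <- switch(normalization,
               sqrtp = u * sqrt(p),
               sump  = p * u / sum(u))
  list(ac = ac, u = u, values = e$values)
}

#' Classify allometry from a one-tailed bound
#'
#' A dimension is negatively allometric (`"-"`) when its one-tailed upper
#' bound lies below 1, positively allometric (`"+"`) when its lower bound
#' lies above 1, and isometric (`"="`) otherwise.
#'
#' @param ac Point allometric coefficient(s).
#' @param bound One-tailed bound(s) on the side of 1 indicated by `side`.
#' @param side `"upper"` or `"lower"`, recycled along `ac`.
#' @return Character vector of `"-"`, `"+"`, `"="`.
#' @export
#' @examples
#' classify_allometry(0.86, 0.88, "upper")  # "-"
#' classify_allometry(1.01, 0.97, "lower")  # "="
#' classify_allometry(1.05, 1.03, "lower")  # "+"
classify_allometry <- function(ac, bound, side) {
  side <- rep_len(side, length(ac))
  out <- rep("=", length(ac))
  out[side == "upper" & bound < 1] <- "-"
  out[side == "lower" & bound > 1] <- "+"
  out
}

#' @export
print.allometry <- function(x, digits = 3L, ...) {
  cat("Multivariate growth allometry: ", x$taxon, "\n", sep = "")
  cat(sprintf("  %d specimens, %d dimensions; B = %d bootstrap replicates (seed %d)\n",
              x$n_used, x$p_used, x$B, x$seed))
  tab <- x$table
  tab$ac <- round(tab$ac, digits)
  tab$bound <- round(tab$bound, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.allometry <- function(object, ...) {
  structure(list(fit = object), class = "summary.allometry")
}

#' @export
print.summary.allometry <- function(x, ...) {
  f <- x$fit
  print(f)
  ev <- f$eigenvalues
  cat(sprintf("\nFirst eigenvector explains %.1f%% of log-scale variance\n",
              100 * ev[1L] / sum(ev)))
  if (f$imputation$cells_imputed > 0L)
    cat(sprintf("Imputation: %d cells, %d iterations, converged: %s\n",
                f$imputation$cells_imputed, f$imputation$iterations,
                f$imputation$converged))
  invisible(x)
}

#' @export
coef.allometry <- function(object, ...) {
  stats::setNames(object$table$ac, object$table$dimension)
}

#' One-tailed allometry bounds
#'
#' @param object An [allometry()] fit.
#' @param parm Dimensions to report (default all).
#' @param level Ignored; the bound level is fixed at fit time (`alpha`).
#' @param ... Unused.
#' @return Data frame with `dimension`, `bound`, `side`.
#' @export
confint.allometry <- function(object, parm = NULL, level = NULL, ...) {
  tab <- object$table[c("dimension", "bound", "side")]
  if (!is.null(parm)) tab <- tab[tab$dimension %in% parm, , drop = FALSE]
  tab
}

#' @export
residuals.allometry <- function(object, ...) {
  # residual log measurements after removing the first (growth) component
  xc <- sweep(object$completed_log, 2L, object$center)
  u <- object$loadings
  xc - (xc %*% u) %*% t(u)
}

#' Plot allometric coefficients with their one-tailed bounds
#'
#' Dot plot of the per-dimension allometric coefficients; arrows run from
#' each point estimate to its one-tailed 95% bound, and the isometry line
#' AC = 1 is dashed.
#'
#' @param x An [allometry()] fit.
#' @param ... Further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.allometry <- function(x, ...) {
  tab <- x$table
  k <- nrow(tab)
  rng <- range(c(tab$ac, tab$bound, 1), na.rm = TRUE)
  graphics::plot(tab$ac, seq_len(k), xlim = rng + c(-0.05, 0.05),
                 yaxt = "n", ylab = "", xlab = "allometric coefficient",
                 pch = 19, main = x$taxon, ...)
  graphics::axis(2, at = seq_len(k), labels = tab$dimension, las = 1)
  graphics::abline(v = 1, lty = 2)
  ok <- !is.na(tab$bound) & abs(tab$bound - tab$ac) > 1e-9
  if (any(ok))
    graphics::arrows(tab$ac[ok], seq_len(k)[ok], tab$bound[ok],
                     seq_len(k)[ok], length = 0.05)
  invisible(x)
}
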