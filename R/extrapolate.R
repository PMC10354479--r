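#' Power-law extrapolation of one skeletal dimension
#'
#' Extrapolates a skeletal dimension from a measured specimen to another
#' wingspan using the allometric relation
#' `Y2 = Y1 * (Z2/Z1)^(b_y/b_z)`, where `b_y` and `b_z` are the allometric
#' coefficients of the dimension and of wingspan.  Computed in log space for
#' numerical stability.
#'
#' @param y1 Dimension length at wingspan `z1` (any length unit).
#' @param z1 Reference wingspan (> 0).
#' @param z2 Target wingspan(s) (> 0); vectorised.
#' @param b_y Allometric coefficient of the dimension.
#' @param b_z Allometric coefficient of wingspan (non-zero).
#' @return Length(s) at `z2`, in the unit of `y1`.
#' @export
#' @examples
#' extrapolate_dimension(100, 1, 7, 0.86, 1.02)  # 100 * 7^(0.86/1.02)
extrapolate_dimension <- function(y1, z1, z2, b_y, b_z) {
  if (any(c(y1, z1, z2) <= 0)) stop("lengths and wingspans must be positive")
  if (b_z == 0) stop("wingspan coefficient b_z must be non-zero")
  exp(log(y1) + (b_y / b_z) * (log(z2) - log(z1)))
}

#' Seed specimen for growth extrapolation
#'
#' Bundles the measured dimensions of one complete specimen with its trunk
#' offsets: L1, the lateral distance from the humeral head to the body
#' midline; L2, the lateral distance from the femoral head to the midline;
#' and L3, the longitudinal distance between the fore- and hindlimb
#' attachments along the midline (all in mm).  Trunk offsets are not skeletal
#' measurements; when not supplied they default to fixed fractions of the
#' seed wingspan (L1 3.5%, L2 2.5%, L3 12%), documented approximations taken
#' from typical published skeletal reconstructions.
#'
#' @param measurements Named numeric vector (mm) containing at least the
#'   seven forelimb elements (so that wingspan is computable), or a one-row
#'   [specimen_table].
#' @param L1,L2,L3 Trunk offsets in mm (optional, see above).
#' @param specimen_id Identifier carried along.
#' @return An object of class `seed_specimen`.
#' @export
seed_specimen <- function(measurements, L1 = NULL, L2 = NULL, L3 = NULL,
                          specimen_id = "seed") {
  if (inherits(measurements, "specimen_table")) {
    stopifnot(nrow(measurements) == 1L)
    specimen_id <- measurements$specimen_id
    v <- unlist(measurements[1, setdiff(names(measurements), "specimen_id")])
    measurements <- v[!is.na(v)]
  }
  z1 <- compute_wingspan(measurements)   # errors if forelimb incomplete
  if (is.null(L1)) L1 <- 0.035 * z1
  if (is.null(L2)) L2 <- 0.025 * z1
  if (is.null(L3)) L3 <- 0.120 * z1
  stopifnot(L1 > 0, L2 > 0, L3 > 0)
  structure(list(specimen_id = specimen_id, measurements = measurements,
                 wingspan_mm = z1, L1 = L1, L2 = L2, L3 = L3),
            class = "seed_specimen")
}

#' Default wingspan grid
#'
#' The default evaluation grid: 0.3 m to 7 m in 0.1 m steps.  Growth-series
#' constructors insert the seed wingspan into the grid so the seed is always
#' reproduced exactly.
#'
#' @return Numeric vector of wingspans in metres.
#' @export
default_wingspan_grid <- function() seq(0.3, 7, by = 0.1)

#' Build a growth series over a wingspan grid
#'
#' Extrapolates every measured dimension of a seed specimen, and the three
#' trunk offsets, across a grid of wingspans.  Each skeletal dimension uses
#' its own allometric coefficient against the wingspan coefficient; trunk
#' offsets L1--L3 grow isometrically (their coefficient is taken equal to the
#' wingspan coefficient), as no ontogenetic data exist for soft-tissue trunk
#' outline widths.
#'
#' @param seed A [seed_specimen()] (or anything accepted by it).
#' @param coefs Named vector of allometric coefficients including an entry
#'   for every measured dimension of the seed and for `wingspan` (the `b_z`
#'   used as denominator).  Typically `coef(fit)` from [allometry()].
#' @param grid Wingspan grid in metres (strictly increasing within
#'   `[0.3, 7]` by default); the seed wingspan is inserted if absent.
#' @param taxon Taxon name carried as metadata.
#' @return An object of class `growth_series`: list with `taxon`,
#'   `wingspan_m` (the grid), `lengths_mm` (dimensions x grid matrix),
#'   `trunk_mm` (3 x grid matrix of L1--L3), `coefs`, `seed`.
#' @seealso [predict.allometry()], [as.data.frame.growth_series()]
#' @export
growth_series <- function(seed, coefs, grid = default_wingspan_grid(),
                          taxon = "unknown") {
  if (!inherits(seed, "seed_specimen")) seed <- seed_specimen(seed)
  stopifnot(is.numeric(coefs), !is.null(names(coefs)))
  if (!"wingspan" %in% names(coefs))
    stop("coefs must include a 'wingspan' entry (b_z)")
  b_z <- coefs[["wingspan"]]
  meas <- seed$measurements
  dims <- setdiff(names(meas), "wingspan")
  need <- setdiff(dims, names(coefs))
  if (length(need))
    stop("no allometric coefficient for dimension(s): ",
         paste(need, collapse = ", "))
  grid <- sort(c(grid, seed$wingspan_mm / 1000))
  grid <- grid[c(TRUE, diff(grid) > 1e-9)]   # collapse near-duplicates
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  z1 <- seed$wingspan_mm / 1000         # single mm -> m conversion point
  lengths <- vapply(dims, function(d) {
    extrapolate_dimension(meas[[d]], z1, grid, coefs[[d]], b_z)
  }, numeric(length(grid)))
  lengths <- t(lengths)                  # dims x grid
  dimnames(lengths) <- list(dims, NULL)
  trunk <- rbind(L1 = extrapolate_dimension(seed$L1, z1, grid, b_z, b_z),
                 L2 = extrapolate_dimension(seed$L2, z1, grid, b_z, b_z),
                 L3 = extrapolate_dimension(seed$L3, z1, grid, b_z, b_z))
  structure(list(taxon = taxon, wingspan_m = grid, lengths_mm = lengths,
                 trunk_mm = trunk, coefs = coefs, seed = seed),
            class = "growth_series")
}

#' Extrapolate a fitted allometry across a wingspan grid
#'
#' `predict()` on an [allometry()] fit builds a [growth_series()] from a seed
#' specimen, using the fitted allometric coefficients (including the fitted
#' wingspan coefficient as `b_z`).
#'
#' @param object An [allometry()] fit whose dimensions include `wingspan`.
#' @param seed A [seed_specimen()] (or measurements accepted by it).
#' @param grid Wingspan grid in metres.
#' @param ... Unused.
#' @return A [growth_series()].
#' @export
predict.allometry <- function(object, seed,
                              grid = default_wingspan_grid(), ...) {
  growth_series(seed, coef(object), grid = grid, taxon = object$taxon)
}

#' @export
print.growth_series <- function(x, ...) {
  cat("Growth series: ", x$taxon, "\n", sep = "")
  cat(sprintf("  %d dimensions over %d wingspans (%.2f-%.2f m); seed at %.3f m\n",
              nrow(x$lengths_mm), length(x$wingspan_m),
              min(x$wingspan_m), max(x$wingspan_m),
              x$seed$wingspan_mm / 1000))
  invisible(x)
}

#' Long-format view of a growth series
#'
#' @param x A [growth_series()].
#' @param ... Unused.
#' @return Data frame with columns `taxon`, `wingspan_m`, `dimension`,
#'   `length_mm` (skeletal dimensions followed by trunk offsets L1--L3).
#' @export
as.data.frame.growth_series <- function(x, ...) {
  m <- rbind(x$lengths_mm, x$trunk_mm)
  data.frame(taxon = x$taxon,
             wingspan_m = rep(x$wingspan_m, each = nrow(m)),
             dimension = rep(rownames(m), times = ncol(m)),
             length_mm = as.vector(m),
             stringsAsFactors = FALSE)
}

# Dimension lengths (mm) at one grid wingspan; errors if Z is off-grid.
series_at <- function(x, z, tol = 1e-9) {
  i <- which(abs(x$wingspan_m - z) < tol)
  if (length(i) != 1L)
    stop("wingspan ", z, " m is not on the series grid")
  list(lengths = x$lengths_mm[, i],
       L1 = x$trunk_mm["L1", i],
       L2 = x$trunk_mm["L2", i],
       L3 = x$trunk_mm["L3", i])
}
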