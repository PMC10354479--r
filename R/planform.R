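# Planform geometry.  Frame: x lateral (away from midline), y longitudinal
# (anterior positive), midline at x = 0; lengths in mm unless stated.

# Rotate 2-vector v by `deg` degrees counter-clockwise.
rot2 <- function(v, deg) {
  a <- deg * pi / 180
  c(cos(a) * v[1L] - sin(a) * v[2L],
    sin(a) * v[1L] + cos(a) * v[2L])
}

# Unit direction of a sweep angle (degrees from +x, posterior positive).
sweep_dir <- function(deg) {
  a <- deg * pi / 180
  c(cos(a), -sin(a))
}

#' Chain the forelimb leading edge
#'
#' Builds the leading-edge polyline by chaining each forelimb element from
#' the shoulder at its posture sweep angle.  Segment order follows the bones:
#' humerus, ulna/radius, metacarpal IV, then the wing phalanges (wp1--wp4, or
#' the combined wp34).
#'
#' @param lengths Named vector of element lengths in mm (all positive).
#' @param posture A [posture()] with an angle for every element.
#' @param shoulder Shoulder position, `c(x, y)` in mm.
#' @return Matrix of joint coordinates, one row per joint from the shoulder
#'   to the wingtip (`length(lengths) + 1` rows).
#' @export
build_leading_edge <- function(lengths, posture, shoulder = c(0, 0)) {
  stopifnot(inherits(posture, "posture"))
  order_all <- c("humerus", "ulna_radius", "mcIV",
                 "wp1", "wp2", "wp3", "wp4", "wp34")
  segs <- order_all[order_all %in% names(lengths)]
  if (!length(segs)) stop("no recognised leading-edge elements in 'lengths'")
  if (any(lengths[segs] <= 0)) stop("non-positive element length")
  need <- setdiff(segs, names(posture$angles))
  if (length(need))
    stop("posture lacks angle(s) for: ", paste(need, collapse = ", "))
  pts <- matrix(NA_real_, nrow = length(segs) + 1L, ncol = 2L)
  pts[1L, ] <- shoulder
  for (i in seq_along(segs)) {
    d <- sweep_dir(posture$angles[[segs[i]]])
    pts[i + 1L, ] <- pts[i, ] + lengths[[segs[i]]] * d
  }
  rownames(pts) <- c("shoulder", segs)
  colnames(pts) <- c("x", "y")
  pts
}

#' Place the hindlimb
#'
#' The femur extends postero-laterally from the hip at the posture's femur
#' angle (45 degrees by default) and the tibia runs straight posteriorly,
#' parallel to the body midline.
#'
#' @param femur,tibia Element lengths in mm (femur > 0; tibia >= 0, zero is
#'   allowed only as a degenerate test case).
#' @param hip Hip position `c(x, y)` in mm.
#' @param posture A [posture()].
#' @return List with `knee` and `ankle` coordinates.
#' @export
build_hindlimb <- function(femur, tibia, hip, posture) {
  stopifnot(inherits(posture, "posture"))
  if (femur <= 0 || tibia < 0) stop("non-positive hindlimb element length")
  knee <- hip + femur * sweep_dir(posture$femur_angle)
  ankle <- knee + tibia * c(0, -1)
  list(knee = knee, ankle = ankle)
}

#' Cubic Bezier trailing edge of the wing membrane
#'
#' The trailing edge runs from the ankle (P0) to the wingtip (P3) as a cubic
#' Bezier curve.  P2 coincides with P3; P1 sits at the intersection of two
#' construction lines: one through the ankle at 30 degrees to the tibia
#' direction (rotated toward the wing) and one through the wingtip at 30
#' degrees to the distalmost wing-finger phalanx (rotated toward the body).
#'
#' @param ankle,wingtip Endpoint coordinates (mm).
#' @param tibia_direction Unit vector along the tibia (pointing distally,
#'   i.e. posteriorly).
#' @param phalanx_direction Unit vector along the distalmost phalanx
#'   (pointing toward the wingtip).
#' @param angle Construction angle in degrees (30 by default).
#' @return Object of class `bezier_edge`: list of control points `P0`...`P3`.
#' @export
trailing_edge <- function(ankle, tibia_direction, wingtip, phalanx_direction,
                          angle = 30) {
  t_dir <- tibia_direction / sqrt(sum(tibia_direction^2))
  p_dir <- phalanx_direction / sqrt(sum(phalanx_direction^2))
  # Of the two lines at `angle` to each axis, take the pair that encloses
  # the membrane: from the ankle the line climbs antero-laterally (30
  # degrees to the tibia axis, tilted toward the wing), from the tip it runs
  # just posterior of the leading edge (30 degrees to the phalanx, tilted
  # toward the body).  This gives the deep root chord and narrow outer wing
  # of pterosaur planform reconstructions.
  d0 <- rot2(-t_dir, -angle)
  d3 <- rot2(p_dir, angle)
  A <- cbind(d0, -d3)
  b <- wingtip - ankle
  det <- A[1L, 1L] * A[2L, 2L] - A[1L, 2L] * A[2L, 1L]
  scale <- max(1, sqrt(sum(b^2)))
  if (abs(det) < 1e-12 * scale)
    stop("trailing-edge construction lines are parallel")
  ts <- solve(A, b)
  P1 <- ankle + ts[1L] * d0
  xr <- range(ankle[1L], wingtip[1L])
  if (P1[1L] < xr[1L] - 1e-9 * scale || P1[1L] > xr[2L] + 1e-9 * scale)
    stop(sprintf(paste0("trailing-edge control point P1 = (%.2f, %.2f) lies ",
                        "outside the wing root-tip x-range [%.2f, %.2f]"),
                 P1[1L], P1[2L], xr[1L], xr[2L]))
  structure(list(P0 = ankle, P1 = P1, P2 = wingtip, P3 = wingtip),
            class = "bezier_edge")
}

#' Sample a cubic Bezier curve
#'
#' Evaluates `B(t) = (1-t)^3 P0 + 3(1-t)^2 t P1 + 3(1-t) t^2 P2 + t^3 P3`
#' at `n` uniformly spaced parameter values, so `B(0) = P0` and `B(1) = P3`.
#'
#' @param edge A [trailing_edge()] (any list with `P0`...`P3` works).
#' @param n Number of samples (>= 2).
#' @return `n` x 2 matrix of points from P0 to P3.
#' @export
bezier_polyline <- function(edge, n = 1024L) {
  stopifnot(n >= 2L)
  t <- seq(0, 1, length.out = n)
  b0 <- (1 - t)^3
  b1 <- 3 * (1 - t)^2 * t
  b2 <- 3 * (1 - t) * t^2
  b3 <- t^3
  cbind(x = b0 * edge$P0[1L] + b1 * edge$P1[1L] +
            b2 * edge$P2[1L] + b3 * edge$P3[1L],
        y = b0 * edge$P0[2L] + b1 * edge$P1[2L] +
            b2 * edge$P2[2L] + b3 * edge$P3[2L])
}

# Proper segment-crossing test between all non-adjacent edges of a closed
# polyline (shared endpoints of consecutive edges are not crossings).
.polygon_is_simple <- function(pts, tol = 1e-9) {
  m <- nrow(pts)
  p <- pts
  q <- pts[c(2:m, 1L), , drop = FALSE]
  cross <- function(ox, oy, ax, ay, bx, by)
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  idx <- utils::combn(m, 2L)
  i <- idx[1L, ]; j <- idx[2L, ]
  adj <- (j - i == 1L) | (i == 1L & j == m)
  i <- i[!adj]; j <- j[!adj]
  d1 <- cross(p[i, 1L], p[i, 2L], q[i, 1L], q[i, 2L], p[j, 1L], p[j, 2L])
  d2 <- cross(p[i, 1L], p[i, 2L], q[i, 1L], q[i, 2L], q[j, 1L], q[j, 2L])
  d3 <- cross(p[j, 1L], p[j, 2L], q[j, 1L], q[j, 2L], p[i, 1L], p[i, 2L])
  d4 <- cross(p[j, 1L], p[j, 2L], q[j, 1L], q[j, 2L], q[i, 1L], q[i, 2L])
  !any(d1 * d2 < -tol & d3 * d4 < -tol)
}

#' Area of a simple closed polyline
#'
#' Shoelace formula; the result is non-negative and in squared input units.
#'
#' @param outline Matrix of vertices (closed implicitly; the last vertex need
#'   not repeat the first).
#' @param check Verify that the outline is simple (non-self-intersecting);
#'   outlines longer than `check_max` vertices are decimated (joints kept)
#'   before the quadratic-time check.
#' @param check_max Vertex budget for the simplicity check.
#' @return Area (scalar).
#' @export
#' @examples
#' planform_area(rbind(c(0, 0), c(4, 0), c(0, 3)))  # 6
planform_area <- function(outline, check = TRUE, check_max = 256L) {
  stopifnot(is.matrix(outline), ncol(outline) == 2L, nrow(outline) >= 3L)
  if (check) {
    pts <- outline
    if (nrow(pts) > check_max) {
      keep <- unique(round(seq(1L, nrow(pts), length.out = check_max)))
      pts <- pts[keep, , drop = FALSE]
    }
    # drop duplicate consecutive vertices (zero-length edges)
    d <- rowSums((pts - pts[c(2:nrow(pts), 1L), , drop = FALSE])^2)
    pts <- pts[d > 1e-18, , drop = FALSE]
    if (nrow(pts) >= 4L && !.polygon_is_simple(pts))
      stop("outline is self-intersecting")
  }
  x <- outline[, 1L]; y <- outline[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  abs(sum(x * yn - xn * y)) / 2
}

#' Assemble a wing planform at one wingspan
#'
#' Places the shoulder at `(L1, 0)` and the hip at `(L2, -L3)`, chains the
#' leading edge and hindlimb, constructs the Bezier trailing edge from the
#' ankle to the wingtip, and closes the single-wing outline along the body
#' midline: midline point (0, 0) -> shoulder -> leading-edge joints ->
#' wingtip -> trailing-edge samples -> ankle -> hip -> (0, -L3) -> close.
#' The single-wing area (shoelace) therefore includes the half-trunk strip
#' to the midline and excludes the uropatagium; wing area is twice the
#' single-wing area and aspect ratio is wingspan^2 / wing area (SI units).
#'
#' @param series A [growth_series()].
#' @param posture A [posture()].
#' @param z Wingspan in metres; must lie on the series grid.
#' @param n Number of Bezier samples used for the outline and its area.
#' @return Object of class `planform`: outline (mm), control points, joint
#'   coordinates, `single_wing_area_m2`, `wing_area_m2`, `aspect_ratio`.
#' @export
build_planform <- function(series, posture, z, n = 1024L) {
  stopifnot(inherits(series, "growth_series"), inherits(posture, "posture"))
  at <- series_at(series, z)
  dims <- at$lengths
  for (el in c("femur", "tibia"))
    if (!el %in% names(dims)) stop("series lacks dimension '", el, "'")
  shoulder <- c(at$L1, 0)
  le <- build_leading_edge(dims, posture, shoulder)
  wingtip <- le[nrow(le), ]
  phalanx_dir <- wingtip - le[nrow(le) - 1L, ]
  hip <- c(at$L2, -at$L3)
  hl <- build_hindlimb(dims[["femur"]], dims[["tibia"]], hip, posture)
  edge <- trailing_edge(hl$ankle, c(0, -1), wingtip, phalanx_dir)
  bez <- bezier_polyline(edge, n)
  # traverse tip -> ankle; drop the duplicated wingtip sample
  bez <- bez[rev(seq_len(n))[-1L], , drop = FALSE]
  outline <- rbind(c(0, 0), le, bez, hip, c(0, -at$L3))
  # simplicity check on a reduced outline that keeps every joint vertex and
  # subsamples only the trailing-edge arc (decimating joints can fake
  # crossings between leading-edge chords and the curve)
  sub <- unique(round(seq(1L, nrow(bez), length.out = 200L)))
  chk <- rbind(c(0, 0), le, bez[sub, , drop = FALSE], hip, c(0, -at$L3))
  dup <- rowSums((chk - chk[c(2:nrow(chk), 1L), , drop = FALSE])^2) <= 1e-18
  chk <- chk[!dup, , drop = FALSE]
  if (!.polygon_is_simple(chk))
    stop("planform outline is self-intersecting")
  area_mm2 <- planform_area(outline, check = FALSE)
  single <- area_mm2 * 1e-6
  wing_area <- 2 * single
  structure(list(taxon = series$taxon, posture = posture$name,
                 wingspan_m = z, outline = outline,
                 joints = le, hip = hip, knee = hl$knee, ankle = hl$ankle,
                 edge = edge,
                 single_wing_area_m2 = single, wing_area_m2 = wing_area,
                 aspect_ratio = z^2 / wing_area),
            class = "planform")
}

#' @export
print.planform <- function(x, ...) {
  cat(sprintf("Planform: %s at %.2f m wingspan (%s posture)\n",
              x$taxon, x$wingspan_m, x$posture))
  cat(sprintf("  wing area %.4f m^2, aspect ratio %.2f\n",
              x$wing_area_m2, x$aspect_ratio))
  invisible(x)
}

#' @export
plot.planform <- function(x, ...) {
  o <- x$outline
  mirror <- cbind(-o[, 1L], o[, 2L])
  xy <- rbind(o, mirror[rev(seq_len(nrow(mirror))), ])
  graphics::plot(xy, type = "n", asp = 1, xlab = "x (mm)", ylab = "y (mm)",
                 main = sprintf("%s, %.2f m", x$taxon, x$wingspan_m), ...)
  graphics::polygon(o, col = "grey85", border = "grey30")
  graphics::polygon(mirror, col = "grey85", border = "grey30")
  invisible(x)
}

#' Wing area and aspect ratio along a growth series
#'
#' Builds a planform at every grid wingspan and collects wing area and
#' aspect ratio.
#'
#' @param series A [growth_series()].
#' @param posture A [posture()].
#' @param n Bezier samples per planform.
#' @return Data frame with `taxon`, `posture`, `wingspan_m`, `wing_area_m2`,
#'   `aspect_ratio`.
#' @export
aspect_ratio_series <- function(series, posture, n = 1024L) {
  rows <- lapply(series$wingspan_m, function(z) {
    pf <- build_planform(series, posture, z, n = n)
    data.frame(taxon = pf$taxon, posture = pf$posture, wingspan_m = z,
               wing_area_m2 = pf$wing_area_m2,
               aspect_ratio = pf$aspect_ratio,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Export a planform as SVG
#'
#' Writes both wings (mirrored about the midline) as a single closed path;
#' the trailing edge uses the native cubic Bezier path command.
#'
#' @param x A [build_planform()] result.
#' @param file Output path.
#' @param scale mm-to-user-unit scale factor.
#' @return `file`, invisibly.
#' @export
write_planform_svg <- function(x, file, scale = 0.1) {
  stopifnot(inherits(x, "planform"))
  fmt <- function(p) sprintf("%.3f %.3f", p[1L] * scale, -p[2L] * scale)
  le <- x$joints
  e <- x$edge
  path_half <- function(sgn) {
    flip <- function(p) c(sgn * p[1L], p[2L])
    parts <- c(sprintf("M %s", fmt(flip(c(0, 0)))),
               vapply(seq_len(nrow(le)), function(i)
                 sprintf("L %s", fmt(flip(le[i, ]))), ""),
               sprintf("C %s, %s, %s", fmt(flip(e$P2)), fmt(flip(e$P1)),
                       fmt(flip(e$P0))),
               sprintf("L %s", fmt(flip(x$hip))),
               sprintf("L %s", fmt(flip(c(0, x$hip[2L])))),
               "Z")
    paste(parts, collapse = " ")
  }
  xs <- range(c(x$outline[, 1L], -x$outline[, 1L])) * scale
  ys <- range(-x$outline[, 2L]) * scale
  pad <- 0.05 * max(diff(xs), diff(ys), 1)
  svg <- c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" viewBox="%.3f %.3f %.3f %.3f">',
                   xs[1L] - pad, ys[1L] - pad,
                   diff(xs) + 2 * pad, diff(ys) + 2 * pad),
           sprintf('<title>%s wing planform, %.2f m wingspan</title>',
                   x$taxon, x$wingspan_m),
           sprintf('<path d="%s" fill="#e8e8e8" stroke="#333" stroke-width="%.3f"/>',
                   path_half(1), pad / 10),
           sprintf('<path d="%s" fill="#e8e8e8" stroke="#333" stroke-width="%.3f"/>',
                   path_half(-1), pad / 10),
           "</svg>")
  writeLines(svg, file)
  invisible(file)
}
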