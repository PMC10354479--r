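# Independent oracles and fixture builders used across the suite.
# Everything here is deliberately written by a different route than the
# package implementation it checks.

# Rank-1 (in centred log space) specimen table: log Y_ij = a_j + b_j * s_i.
make_rank1_table <- function(n = 20, b = rep(1, 5), a = NULL,
                             s = seq(0, 1, length.out = n),
                             dims = head(c("humerus", "ulna_radius", "mcIV",
                                           "wp1", "wp2", "wp3", "wp4",
                                           "femur", "tibia", "wingspan",
                                           "skull", "neck", "tail"),
                                         length(b)),
                             taxon = "synthetic") {
  if (is.null(a)) a <- seq(2, 3, length.out = length(b))
  m <- exp(outer(s, b) + matrix(a, n, length(b), byrow = TRUE))
  colnames(m) <- dims
  specimen_table(sprintf("s%03d", seq_len(n)), as.data.frame(m), taxon)
}

# Exact area of a region bounded by straight polyline edges and one cubic
# Bezier arc, via Green's theorem: A = 1/2 * closed integral of (x dy - y dx).
# The Bezier contribution is integrated in closed form from the Bernstein
# polynomial coefficients; this is independent of any sampling.
bezier_green_term <- function(P0, P1, P2, P3) {
  # power-basis coefficients of x(t), y(t)
  coefs <- function(p0, p1, p2, p3)
    c(p0, 3 * (p1 - p0), 3 * (p0 - 2 * p1 + p2), p3 - p0 + 3 * (p1 - p2))
  cx <- coefs(P0[1], P1[1], P2[1], P3[1])
  cy <- coefs(P0[2], P1[2], P2[2], P3[2])
  dx <- cx[-1] * 1:3                       # derivative coefficients
  dy <- cy[-1] * 1:3
  polymul <- function(u, v) {
    out <- numeric(length(u) + length(v) - 1L)
    for (i in seq_along(u))
      out[i + seq_along(v) - 1L] <- out[i + seq_along(v) - 1L] + u[i] * v
    out
  }
  integ01 <- function(u) sum(u / seq_along(u))
  0.5 * (integ01(polymul(cx, dy)) - integ01(polymul(cy, dx)))
}

segment_green_term <- function(p, q) 0.5 * (p[1] * q[2] - q[1] * p[2])

# Exact area of a planform: straight edges midline -> shoulder -> joints ->
# wingtip, Bezier wingtip -> ankle (the trailing edge reversed), then
# ankle -> hip -> midline -> close.
exact_planform_area <- function(pf) {
  verts <- rbind(c(0, 0), pf$joints)
  total <- 0
  for (i in seq_len(nrow(verts) - 1L))
    total <- total + segment_green_term(verts[i, ], verts[i + 1L, ])
  e <- pf$edge
  # trailing edge traversed tip -> ankle: reversed control order
  total <- total + bezier_green_term(e$P3, e$P2, e$P1, e$P0)
  tail_pts <- rbind(pf$ankle, pf$hip, c(0, pf$hip[2]), c(0, 0))
  for (i in seq_len(nrow(tail_pts) - 1L))
    total <- total + segment_green_term(tail_pts[i, ], tail_pts[i + 1L, ])
  abs(total)
}

# Closed-form minimum power speed when profile power is speed-independent.
vmp_closed_form <- function(mass, z, cfg = aero_config()) {
  A <- cfg$k * (mass * cfg$g)^2 / (2 * cfg$rho * pi * z^2 / 4)
  B <- 0.5 * cfg$rho * (cfg$sb_coef * mass^cfg$sb_exp) * cfg$c_db
  (A / (3 * B))^0.25
}

# Slow, transparent exact sign-flip enumeration (recursive), independent of
# the package's vectorised implementation.
exact_signflip_p <- function(d) {
  n <- length(d)
  t_obs <- abs(mean(d))
  tol <- 1e-12 * max(abs(d))
  count <- function(i, acc) {
    if (i > n) return(as.integer(abs(acc / n) >= t_obs - tol))
    count(i + 1L, acc + d[i]) + count(i + 1L, acc - d[i])
  }
  count(1L, 0) / 2^n
}

# Growth series with known coefficients from a preset configuration,
# seeded at the upper anchor specimen.
preset_series <- function(cfg, grid = default_wingspan_grid()) {
  tab <- generate_taxon(cfg)
  sd_ <- pterowing:::pick_seed(tab, combine_wp34 = cfg$combine_wp34)
  b <- cfg$b
  if (cfg$combine_wp34)
    b <- c(b[setdiff(names(b), c("wp3", "wp4"))], wp34 = unname(b[["wp3"]]))
  growth_series(sd_, b, grid = grid, taxon = cfg$taxon)
}
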