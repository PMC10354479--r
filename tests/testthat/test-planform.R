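neutral <- posture_preset("neutral")

test_that("leading edge chains segments at their sweep angles", {
  zero <- posture(c(humerus = 0, ulna_radius = 0, mcIV = 0, wp1 = 0,
                    wp2 = 0, wp3 = 0, wp4 = 0))
  lens <- stats::setNames(rep(100, 7),
                          c("humerus", "ulna_radius", "mcIV",
                            "wp1", "wp2", "wp3", "wp4"))
  le <- build_leading_edge(lens, zero, shoulder = c(10, 5))
  expect_equal(unname(le[nrow(le), ]), c(710, 5))
  # single segment at 30 degrees: hand trigonometry
  one <- build_leading_edge(c(humerus = 100),
                            posture(c(humerus = 30)), c(0, 0))
  expect_equal(unname(one["humerus", ]), c(100 * cos(pi / 6), -50),
               tolerance = 1e-12)
  # near-vertical limit: wingtip approaches (0, -700)
  steep <- posture(stats::setNames(rep(89.99, 7), names(lens)))
  tip <- build_leading_edge(lens, steep, c(0, 0))
  expect_equal(unname(tip[nrow(tip), ]), c(0, -700), tolerance = 0.2)
  expect_error(build_leading_edge(c(humerus = -5),
                                  posture(c(humerus = 0))), "non-positive")
})

test_that("hindlimb placement decomposes the femur at 45 degrees", {
  hl <- build_hindlimb(100, 100, hip = c(50, 0), posture = neutral)
  expect_equal(hl$knee, c(50 + 100 / sqrt(2), -100 / sqrt(2)))
  expect_equal(hl$ankle, c(50 + 100 / sqrt(2), -100 / sqrt(2) - 100))
  # degenerate tibia allowed for testing
  expect_equal(build_hindlimb(100, 0, c(0, 0), neutral)$ankle,
               build_hindlimb(100, 0, c(0, 0), neutral)$knee)
  # doubling both lengths doubles the hip -> ankle displacement
  a1 <- build_hindlimb(80, 90, c(10, -5), neutral)$ankle - c(10, -5)
  a2 <- build_hindlimb(160, 180, c(10, -5), neutral)$ankle - c(10, -5)
  expect_equal(a2, 2 * a1)
})

test_that("trailing edge control points solve the 30-degree construction", {
  ankle <- c(60, -150)
  wingtip <- c(700, -120)
  phal <- c(cos(-50 * pi / 180), sin(-50 * pi / 180))
  e <- trailing_edge(ankle, c(0, -1), wingtip, phal)
  expect_identical(e$P2, e$P3)       # P2 coincides with P3 by definition
  expect_equal(e$P0, ankle)
  expect_equal(e$P3, wingtip)
  # independent 2x2 linear-solve oracle with explicit line directions
  deg <- pi / 180
  d0 <- c(sin(30 * deg), cos(30 * deg))          # antero-lateral from ankle
  ph_ang <- -50 * deg
  # tip line 30 degrees anticlockwise of the phalanx: the membrane side
  d3 <- c(cos(ph_ang + 30 * deg), sin(ph_ang + 30 * deg))
  ts <- solve(cbind(d0, -d3), wingtip - ankle)
  expect_equal(e$P1, ankle + ts[1] * d0, tolerance = 1e-10)
  # the P1 line residuals: P1 lies on both construction lines
  r0 <- e$P1 - ankle
  expect_lt(abs(r0[1] * d0[2] - r0[2] * d0[1]), 1e-6)
  r3 <- e$P1 - wingtip
  expect_lt(abs(r3[1] * d3[2] - r3[2] * d3[1]), 1e-6)
  # translation equivariance
  sh <- c(-35, 12)
  e2 <- trailing_edge(ankle + sh, c(0, -1), wingtip + sh, phal)
  expect_equal(e2$P1, e$P1 + sh, tolerance = 1e-9)
})

test_that("degenerate trailing-edge constructions error", {
  # parallel construction lines
  expect_error(trailing_edge(c(0, 0), c(0, -1), c(100, 0),
                             c(sin(-60 * pi / 180), -cos(-60 * pi / 180))),
               "parallel|outside")
  # intersection beyond the wingtip in x (hand-solved: P1 at x = 81.6)
  expect_error(trailing_edge(c(0, 0), c(0, -1), c(10, 100), c(1, 0)),
               "outside")
})

test_that("Bezier sampling interpolates its endpoints and stays collinear
           for collinear control points", {
  e <- list(P0 = c(0, 0), P1 = c(1, 2), P2 = c(3, 1), P3 = c(3, 1))
  bz <- bezier_polyline(e, 7)
  expect_equal(unname(bz[1, ]), e$P0)
  expect_equal(unname(bz[7, ]), e$P3)
  # all control points equal: every sample equal
  same <- list(P0 = c(2, 2), P1 = c(2, 2), P2 = c(2, 2), P3 = c(2, 2))
  bs <- bezier_polyline(same, 5)
  expect_true(all(bs[, 1] == 2 & bs[, 2] == 2))
  # collinear control points: samples collinear to 1e-9
  col <- list(P0 = c(0, 0), P1 = c(1, 1), P2 = c(2.5, 2.5), P3 = c(4, 4))
  bc <- bezier_polyline(col, 101)
  expect_lt(max(abs(bc[, 2] - bc[, 1])), 1e-9)
})

test_that("shoelace area is exact on hand-checked polygons and rejects
           self-intersections", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(planform_area(sq), 1)
  tri <- rbind(c(0, 0), c(4, 0), c(0, 3))
  expect_equal(planform_area(tri), 6)
  bowtie <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))
  expect_error(planform_area(bowtie), "self-intersecting")
  # rigid motions leave the area unchanged
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  moved <- sweep(tri %*% t(R), 2, c(-11, 23), `+`)
  expect_equal(planform_area(moved), 6, tolerance = 1e-12)
})

test_that("sampled areas converge and agree with the exact Green's-theorem
           area", {
  ser <- preset_series(preset_library()[["Rhamphorhynchus"]])
  for (z in c(0.5, 3, 7)) {
    pf1 <- build_planform(ser, neutral, z, n = 1024)
    pf2 <- build_planform(ser, neutral, z, n = 2048)
    expect_lt(abs(pf1$wing_area_m2 - pf2$wing_area_m2) / pf2$wing_area_m2,
              1e-4)
    exact <- exact_planform_area(pf1) * 1e-6 * 2
    expect_lt(abs(pf1$wing_area_m2 - exact) / exact, 5e-4)
  }
})

test_that("uniform scaling quadruples wing area and preserves aspect ratio", {
  m <- c(humerus = 50, ulna_radius = 80, mcIV = 30, wp1 = 100, wp2 = 85,
         wp3 = 70, wp4 = 60, femur = 28, tibia = 36)
  b <- stats::setNames(rep(1, 10), c(names(m), "wingspan"))
  s1 <- growth_series(seed_specimen(m), b, taxon = "T")
  s2 <- growth_series(seed_specimen(2 * m), b, taxon = "T")
  z1 <- s1$seed$wingspan_mm / 1000
  p1 <- build_planform(s1, neutral, z1)
  p2 <- build_planform(s2, neutral, 2 * z1)
  expect_equal(p2$wing_area_m2, 4 * p1$wing_area_m2, tolerance = 1e-9)
  expect_equal(p2$aspect_ratio, p1$aspect_ratio, tolerance = 1e-9)
})

test_that("isometric growth keeps aspect ratio constant along the grid", {
  m <- c(humerus = 50, ulna_radius = 80, mcIV = 30, wp1 = 100, wp2 = 85,
         wp3 = 70, wp4 = 60, femur = 28, tibia = 36)
  b <- stats::setNames(rep(1, 10), c(names(m), "wingspan"))
  ser <- growth_series(seed_specimen(m), b, taxon = "T")
  ar <- aspect_ratio_series(ser, neutral, n = 256)$aspect_ratio
  expect_lt(diff(range(ar)) / ar[1], 1e-9)
})

test_that("neutral and taxon-specific postures agree on the direction of
           clear aspect-ratio trends", {
  for (nm in c("Pteranodon", "Sinopterus", "Pterodactylus")) {
    cfg <- preset_library()[[nm]]
    ser <- preset_series(cfg, grid = seq(0.3, 7, by = 0.335))
    trend <- vapply(list(posture_preset(nm, cfg$combine_wp34),
                         posture_preset("neutral", cfg$combine_wp34)),
                    function(po) {
                      ar <- aspect_ratio_series(ser, po, n = 256)$aspect_ratio
                      (ar[length(ar)] - ar[1]) / ar[1]
                    }, numeric(1))
    expect_gt(abs(trend[1]), 0.05)      # the trend is a clear one
    expect_identical(sign(trend[1]), sign(trend[2]))
  }
})

test_that("SVG export writes a two-wing closed-path document", {
  ser <- preset_series(preset_library()[["Pteranodon"]])
  pf <- build_planform(ser, posture_preset("Pteranodon"), 7)
  f <- withr::local_tempfile(fileext = ".svg")
  write_planform_svg(pf, f)
  svg <- readLines(f)
  expect_true(any(grepl("<svg", svg)))
  expect_identical(sum(grepl("<path", svg)), 2L)
  expect_true(all(grepl(" C ", svg[grepl("<path", svg)])))
})
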