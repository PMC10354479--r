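test_that("generation is deterministic under its seed", {
  cfg <- preset_library()[["Pterodactylus"]]
  t1 <- generate_taxon(cfg)
  t2 <- generate_taxon(cfg)
  expect_identical(t1, t2)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_specimen_table(t1, f1)
  write_specimen_table(t2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("noise-free isometric generation yields AC = 1 on every
           dimension", {
  b <- stats::setNames(rep(1, 13), dimension_vocabulary())
  cfg <- synthetic_taxon_config("iso", n = 20, b = b,
                                size_range = c(0.3, 1.3), sigma = 0,
                                seed = 2)
  fit <- allometry(generate_taxon(cfg), boot = 0)
  expect_equal(unname(coef(fit)), rep(1, 13), tolerance = 1e-8)
})

test_that("noise-free tables are rank 2 in raw log space (size plus
           intercept)", {
  cfg <- synthetic_taxon_config("r2", n = 15,
                                b = c(humerus = 0.9, ulna_radius = 1.1,
                                      mcIV = 0.8, wp1 = 1, wp2 = 1.2,
                                      wp3 = 1, wp4 = 0.7, wingspan = 1,
                                      femur = 0.9, tibia = 1.1),
                                size_range = c(0.3, 1.3), sigma = 0,
                                seed = 3)
  tab <- generate_taxon(cfg)
  lx <- log(as.matrix(tab[, -1]))
  sv <- svd(cbind(1, lx))$d
  expect_lt(sv[3] / sv[1], 1e-12)
})

test_that("the MCAR deletion rate matches its binomial expectation", {
  b <- stats::setNames(rep(1, 13), dimension_vocabulary())
  cfg <- synthetic_taxon_config("m", n = 100, b = b,
                                size_range = c(0.3, 1.3), sigma = 0.05,
                                missing_rate = 0.2, seed = 4)
  tab <- generate_taxon(cfg)
  # deletable cells: all dimensions except wingspan, non-anchor rows
  del <- as.matrix(tab[-(1:2), setdiff(dimension_vocabulary(), "wingspan")])
  frac <- mean(is.na(del))
  se <- sqrt(0.2 * 0.8 / length(del))
  expect_lt(abs(frac - 0.2), 3 * se)
  # the wingspan column is never deleted
  expect_false(anyNA(tab$wingspan))
})

test_that("complete-specimen wingspans span and respect the configured
           range", {
  for (nm in c("Rhamphorhynchus", "Pterodactylus", "Sinopterus")) {
    cfg <- preset_library()[[nm]]
    ws <- table_wingspans(generate_taxon(cfg), "m")
    ws <- ws[!is.na(ws)]
    expect_gte(min(ws), cfg$size_range[1] - 1e-9)
    expect_lte(max(ws), cfg$size_range[2] + 1e-9)
    # anchors sit exactly at the bounds
    expect_equal(min(ws), cfg$size_range[1], tolerance = 1e-9)
    expect_equal(max(ws), cfg$size_range[2], tolerance = 1e-9)
  }
})

test_that("preset coefficient vectors carry the published values", {
  pr <- preset_library()
  expect_equal(pr$Pteranodon$b[["humerus"]], 1.18)
  expect_equal(pr$Pteranodon$b[["mcIV"]], 1.23)
  expect_equal(pr$Sinopterus$b[["femur"]], 1.26)
  expect_equal(pr$Rhamphorhynchus$b[["humerus"]], 0.86)
  expect_equal(pr$Pterodactylus$b[["tibia"]], 1.06)
  for (cfg in pr) {
    expect_true(cfg$b[["wingspan"]] >= 0.85 && cfg$b[["wingspan"]] <= 1.02)
    expect_true(all(cfg$b > 0))
  }
  # sample sizes and ranges mirror the published compilations
  expect_identical(vapply(pr, function(x) x$n, 1L),
                   c(Rhamphorhynchus = 88L, Pterodactylus = 22L,
                     Sinopterus = 10L, Pteranodon = 59L,
                     anurognathids = 16L))
  expect_equal(pr$Rhamphorhynchus$size_range, c(0.30, 1.28))
  expect_equal(pr$Pterodactylus$size_range, c(0.19, 0.74))
})

test_that("preset coefficient vectors close the Jolicoeur norm constraint", {
  for (cfg in preset_library()) {
    b <- cfg$b
    if (cfg$combine_wp34) {
      b <- c(b[setdiff(names(b), c("wp3", "wp4"))],
             wp34 = unname(b[["wp3"]]))
    }
    expect_equal(sum(b^2), length(b),
                 tolerance = if (cfg$taxon == "Pteranodon") 2e-3 else 1e-9)
  }
})

test_that("generated tables recover their generating coefficients", {
  cfg <- preset_library()[["Rhamphorhynchus"]]
  cfg$n <- 60L
  fit <- allometry(generate_taxon(cfg), boot = 0)
  err <- coef(fit) - cfg$b[fit$table$dimension]
  expect_lt(max(abs(err)), 0.05)
})

test_that("simulate() on a fit round-trips the fitted coefficients", {
  cfg <- preset_library()[["Rhamphorhynchus"]]
  cfg$missing_rate <- 0
  fit <- allometry(generate_taxon(cfg), boot = 0)
  tabs <- simulate(fit, nsim = 2, seed = 9)
  expect_length(tabs, 2)
  refit <- allometry(tabs[[1]], boot = 0)
  expect_equal(coef(refit), coef(fit), tolerance = 0.08)
})

test_that("the preset library serialises to YAML and postures round-trip", {
  f <- withr::local_tempfile(fileext = ".yaml")
  write_presets_yaml(f)
  y <- yaml::read_yaml(f)
  expect_identical(names(y), names(preset_library()))
  expect_equal(y$Pteranodon$b$humerus, 1.18)
  po <- posture_preset("Pteranodon")
  fp <- withr::local_tempfile(fileext = ".yaml")
  write_posture_yaml(po, fp)
  po2 <- read_posture_yaml(fp)
  expect_equal(po2$angles, po$angles)
  expect_identical(po2$name, po$name)
})
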