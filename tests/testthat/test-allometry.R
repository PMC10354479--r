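test_that("noiseless isometric data give AC = 1 everywhere, class =", {
  tab <- make_rank1_table(n = 12, b = rep(1, 6))
  fit <- allometry(tab, boot = 100, seed = 1)
  expect_equal(unname(coef(fit)), rep(1, 6), tolerance = 1e-8)
  expect_equal(fit$table$bound, rep(1, 6), tolerance = 1e-8)
  expect_true(all(fit$table$class == "="))
  # the alternative normalisation also reduces to 1 under isometry
  fit2 <- allometry(tab, boot = 0, normalization = "sump")
  expect_equal(unname(coef(fit2)), rep(1, 6), tolerance = 1e-8)
})

test_that("two noiseless dimensions with slope 2 match the hand eigenvector", {
  # log y2 = 2 log y1 + c: covariance [[v,2v],[2v,4v]], eigenvector
  # (1,2)/sqrt(5), AC = sqrt(2) * (1,2)/sqrt(5)
  tab <- make_rank1_table(n = 10, b = c(1, 2), dims = c("humerus", "femur"))
  fit <- allometry(tab, boot = 0)
  expect_equal(unname(coef(fit)), sqrt(2) * c(1, 2) / sqrt(5),
               tolerance = 1e-10)
  expect_equal(unname(coef(fit)[2] / coef(fit)[1]), 2, tolerance = 1e-10)
})

test_that("rank-1 data reproduce the generating slopes up to normalisation", {
  set.seed(3)
  b <- c(0.8, 0.9, 1, 1.1, 1.25)
  tab <- make_rank1_table(n = 15, b = b)
  fit <- allometry(tab, boot = 0)
  # oracle: eigenvector of the rank-1 covariance is b/||b||, so the AC
  # vector is b * sqrt(p)/||b||
  expect_equal(unname(coef(fit)), b * sqrt(5) / sqrt(sum(b^2)),
               tolerance = 1e-9)
})

test_that("the AC vector over sqrt(p) always has unit norm", {
  for (seed in 1:5) {
    cfg <- synthetic_taxon_config("t", n = 25,
                                  b = c(humerus = 0.9, ulna_radius = 1.1,
                                        mcIV = 1, wp1 = 0.95, wp2 = 1.2,
                                        wp3 = 1, wp4 = 0.8,
                                        wingspan = 1, femur = 0.85,
                                        tibia = 1.05),
                                  size_range = c(0.3, 1.2), sigma = 0.08,
                                  missing_rate = 0.15, seed = seed)
    fit <- allometry(generate_taxon(cfg), boot = 0)
    expect_equal(sum((coef(fit) / sqrt(fit$p_used))^2), 1, tolerance = 1e-10)
  }
})

test_that("estimates are invariant to rescaling any single dimension", {
  cfg <- synthetic_taxon_config("t", n = 30,
                                b = c(humerus = 0.9, ulna_radius = 1.1,
                                      mcIV = 1, wp1 = 1, wp2 = 1, wp3 = 1,
                                      wp4 = 1, wingspan = 1, femur = 0.9,
                                      tibia = 1.1),
                                size_range = c(0.3, 1.2), sigma = 0.05,
                                seed = 11)
  tab <- generate_taxon(cfg)
  fit <- allometry(tab, boot = 0)
  tab2 <- tab
  tab2$femur <- tab2$femur * 25.4        # unit change on one dimension
  fit2 <- allometry(tab2, boot = 0)
  expect_equal(coef(fit2), coef(fit), tolerance = 1e-9)
})

test_that("classification follows the one-tailed bound rule", {
  expect_identical(classify_allometry(0.86, 0.88, "upper"), "-")
  expect_identical(classify_allometry(1.01, 0.97, "lower"), "=")
  expect_identical(classify_allometry(1.05, 1.03, "lower"), "+")
  expect_identical(classify_allometry(0.95, 1.01, "upper"), "=")
  # bound side is set by the point estimate
  cfg <- preset_library()[["Rhamphorhynchus"]]
  fit <- allometry(generate_taxon(cfg), boot = 150, seed = 2)
  tab <- fit$table
  expect_true(all(tab$side[tab$ac < 1] == "upper"))
  expect_true(all(tab$side[tab$ac >= 1] == "lower"))
})

test_that("degenerate fits raise informative errors", {
  m <- data.frame(humerus = c(10, 20), femur = c(5, 7))
  expect_error(allometry(specimen_table(c("a", "b"), m, "T"), boot = 0),
               "fewer than 3")
  m <- data.frame(humerus = c(10, 10, 10), femur = c(5, 6, 7))
  expect_error(allometry(specimen_table(c("a", "b", "c"), m, "T"), boot = 0),
               "zero-variance.*humerus")
})

test_that("wp3+wp4 can be analysed as one combined dimension", {
  cfg <- preset_library()[["anurognathids"]]
  fit <- allometry(generate_taxon(cfg), combine_wp34 = TRUE, boot = 0)
  expect_true("wp34" %in% fit$table$dimension)
  expect_false(any(c("wp3", "wp4") %in% fit$table$dimension))
  # the combined dimension tracks the shared generating coefficient (1.33,
  # relative to b_z = 1) closely
  expect_equal(unname(coef(fit)[["wp34"]] / coef(fit)[["wingspan"]]),
               1.33, tolerance = 0.1)
})

test_that("one-sided bootstrap bounds exclude the truth at about the
           nominal 5% rate", {
  b <- c(humerus = 0.86, ulna_radius = 0.89, mcIV = 0.74, wp1 = 1.07,
         wp2 = 1.13, wp3 = 1.13, wp4 = 1.01, wingspan = 1.02,
         femur = 0.87, tibia = 1.05)
  n_rep <- 200
  excl <- 0L
  total <- 0L
  for (r in seq_len(n_rep)) {
    cfg <- synthetic_taxon_config("t", n = 60, b = b,
                                  size_range = c(0.3, 1.28), sigma = 0.05,
                                  seed = 5000 + r, anchor = FALSE)
    fit <- allometry(generate_taxon(cfg), boot = 1000, seed = r)
    tab <- fit$table
    b_true <- b[tab$dimension]
    # normalise the truth the same way the estimator is normalised
    b_true <- b_true * sqrt(length(b_true)) / sqrt(sum(b_true^2))
    out <- ifelse(tab$side == "upper", b_true > tab$bound,
                  b_true < tab$bound)
    excl <- excl + sum(out)
    total <- total + length(out)
  }
  rate <- excl / total
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.10)
})

test_that("coefficients are recovered within 0.05 in at least 95% of runs", {
  b <- c(humerus = 0.86, ulna_radius = 0.89, mcIV = 0.74, wp1 = 1.07,
         wp2 = 1.13, wp3 = 1.13, wp4 = 1.01, wingspan = 1.02,
         femur = 0.87, tibia = 1.05)
  # the estimator targets the Jolicoeur-normalised vector b * sqrt(p)/||b||
  b_target <- b * sqrt(length(b) / sum(b^2))
  ok <- logical(100)
  for (r in seq_len(100)) {
    cfg <- synthetic_taxon_config("t", n = 60, b = b,
                                  size_range = c(0.3, 1.28), sigma = 0.05,
                                  missing_rate = 0.1, seed = 100 + r)
    fit <- allometry(generate_taxon(cfg), boot = 0)
    err <- coef(fit) - b_target[fit$table$dimension]
    ok[r] <- all(abs(err) <= 0.05)
  }
  expect_gte(mean(ok), 0.95)
})
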