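test_that("pedigree generation matches the configured family-structure mix", {
  peds <- generate_pedigrees(223, seed = 10)
  n_sub <- sum(vapply(peds, nrow, integer(1)))
  expect_gte(n_sub, 700); expect_lte(n_sub, 810)
  ## determinism under a fixed seed
  p1 <- generate_pedigrees(1, seed = 77)[[1]]
  p2 <- generate_pedigrees(1, seed = 77)[[1]]
  expect_identical(as.data.frame(p1), as.data.frame(p2))
  ## different seed, same marginal mix of family sizes within MC error
  sizes <- vapply(generate_pedigrees(1000, seed = 11), nrow, integer(1))
  expect_equal(mean(sizes), 3.37, tolerance = 0.05)
  expect_gt(mean(sizes >= 8), 0.005)         # extended families present
  ## every family spans at least two generations
  expect_true(all(vapply(peds, function(p) any(!is.na(p$father_id)),
                         logical(1))))
  expect_error(generate_pedigrees(0), class = "jx_argument_error")
})

test_that("gene dropping respects allele frequency and Mendelian transmission", {
  peds <- generate_pedigrees(300, seed = 2)
  expect_true(all(simulate_genotypes(peds, maf = 0, seed = 3) == 0))
  ## founder allele frequency
  big <- generate_pedigrees(3000, seed = 4)
  x <- simulate_genotypes(big, maf = 0.25, seed = 5)
  founders <- unlist(lapply(big, function(p) is.na(p$father_id)))
  n_founder <- sum(founders)
  freq <- sum(x[founders]) / (2 * n_founder)
  expect_lt(abs(freq - 0.25), 3 * sqrt(0.25 * 0.75 / (2 * n_founder)))
  ## Mendelian audit on every offspring
  x2 <- simulate_genotypes(peds, maf = 0.4, seed = 6)
  off <- 0L
  for (k in seq_along(peds)) {
    ped <- peds[[k]]
    rows <- off + seq_len(nrow(ped)); off <- off + nrow(ped)
    xi <- x2[rows]
    for (i in which(!is.na(ped$father_id))) {
      xf <- xi[match(ped$father_id[i], ped$id)]
      xm <- xi[match(ped$mother_id[i], ped$id)]
      expect_gte(xi[i], (xf == 2) + (xm == 2))
      expect_lte(xi[i], 2 - (xf == 0) - (xm == 0))
    }
  }
})

test_that("dichotomous exposure has marginal prevalence one half with familial clustering", {
  cfg <- scenario_config("transition1", "dichotomous", seed = 1)
  peds <- generate_pedigrees(30000, seed = 8)
  e <- simulate_exposure(peds, cfg, seed = 9)
  n <- length(e)
  expect_gt(n, 95000)
  expect_lt(abs(mean(e) - 0.5), 3 * sqrt(0.25 / n))
  ## familial clustering: within-family pair correlation is positive
  fam <- rep(seq_along(peds), vapply(peds, nrow, integer(1)))
  fm <- tapply(e, fam, mean)
  fs <- tabulate(fam)
  expect_gt(var(fm[fs == 3]), 0.25 / 3 * 1.2)
})

test_that("continuous exposure hits the configured population quartiles and declines with age", {
  cfg <- scenario_config("transition1", "continuous", seed = 1)
  peds <- generate_pedigrees(30000, seed = 12)
  e <- simulate_exposure(peds, cfg, seed = 13)
  q <- quantile(e, c(0.25, 0.75))
  expect_lt(abs(q[1] - 140), 5)
  expect_lt(abs(q[2] - 280), 5)
  expect_true(all(e >= 0))
  age <- unlist(lapply(peds, `[[`, "age"))
  expect_lt(cor(age, e), 0)
  ## no family effect (and no age trend, which otherwise makes families
  ## systematically alike in composition) -> no clustering of the score
  cfg0 <- cfg; cfg0$exposure_sd <- 0; cfg0$exposure_age_slope <- 0
  e0 <- simulate_exposure(peds, cfg0, seed = 14)
  fam <- rep(seq_along(peds), vapply(peds, nrow, integer(1)))
  ## compare variance of size-3 family means with the independence value
  v_within <- var(e0)
  fm <- tapply(e0, fam, mean); fs <- tabulate(fam)
  expect_equal(var(fm[fs == 3]) / (v_within / 3), 1, tolerance = 0.15)
})

test_that("phenotype simulation reduces to the closed-form logit in the degenerate case", {
  cfg <- scenario_config("transition1", "dichotomous",
                         coefficients = list(
                           alpha = c(a0 = -1, a1 = 0, a2 = 0, a3 = 0, a4 = 0),
                           gamma = c(g0 = -1.5, g1 = 0, g2 = 0, g3 = 0,
                                     g4 = 0, g5 = 0, g6 = 0, g7 = 0, g8 = 0)),
                         random_sd = c(y1 = 0, y2 = 0), seed = 1)
  peds <- generate_pedigrees(30000, seed = 15)
  n <- sum(vapply(peds, nrow, integer(1)))
  ph <- simulate_phenotypes(peds, rep(0, n), rep(0, n), cfg, seed = 16)
  expect_lt(abs(mean(ph$Y1) - plogis(-1)), 3 * sqrt(0.25 / n))
  expect_lt(abs(mean(ph$Y2) - plogis(-1.5)), 3 * sqrt(0.25 / n))
})

test_that("uncalibrated intercepts are refused", {
  cfg <- scenario_config("transition1", "dichotomous", seed = 1)
  peds <- generate_pedigrees(5, seed = 1)
  n <- sum(vapply(peds, nrow, integer(1)))
  expect_error(simulate_phenotypes(peds, rep(0, n), rep(0, n), cfg),
               class = "jx_config_error")
})

test_that("intercept calibration equals the analytic logit without covariates or random effects", {
  cfg <- scenario_config("transition1", "dichotomous",
                         coefficients = list(
                           alpha = c(a1 = 0, a2 = 0, a3 = 0, a4 = 0),
                           gamma = c(g1 = 0, g2 = 0, g3 = 0, g5 = 0,
                                     g6 = 0, g7 = 0, g8 = 0)),
                         random_sd = c(y1 = 0, y2 = 0),
                         targets = c(y1 = 0.5, y2_given_y1_0 = 0.2,
                                     y2_given_y1_1 = 0.7),
                         seed = 1)
  cfg <- calibrate_intercepts(cfg, n = 2000)
  expect_equal(unname(cfg$coefficients$alpha["a0"]), 0, tolerance = 1e-6)
  expect_equal(unname(cfg$coefficients$gamma["g0"]), qlogis(0.2),
               tolerance = 1e-6)
  expect_equal(unname(cfg$coefficients$gamma["g0"] +
                      cfg$coefficients$gamma["g4"]), qlogis(0.7),
               tolerance = 1e-6)
  expect_error(calibrate_intercepts(cfg, targets = c(y1 = 1.2)),
               class = "jx_argument_error")
})

test_that("default transition-1 calibration reproduces the target marginal prevalences", {
  cfg <- .cached_cfg("transition1", "dichotomous")
  big <- cfg; big$n_families <- 15000
  dat <- simulate_dataset(big)
  expect_equal(mean(dat$Y1), 0.292, tolerance = 0.02)
  expect_equal(mean(dat$Y2), 0.199, tolerance = 0.03)
  expect_equal(mean(dat$Y2[dat$Y1 == 1]), 0.605, tolerance = 0.03)
  expect_equal(mean(dat$Y2[dat$Y1 == 0]), 0.032, tolerance = 0.15)
})

test_that("a fixed seed yields a bit-identical dataset and the null variant is unlinked", {
  cfg <- .cached_cfg("transition1", "dichotomous")
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  expect_true("X_null" %in% names(d1))
  expect_lt(abs(cor(d1$X, d1$X_null)), 0.1)
})

test_that("unknown coefficient names are rejected by the configuration", {
  expect_error(scenario_config("transition1",
                               coefficients = list(alpha = c(zz = 1))),
               class = "jx_config_error")
  expect_error(scenario_config("polytomous",
                               coefficients = list(gamma = c(g1 = 0))),
               class = "jx_config_error")
  expect_error(scenario_config("transition1", maf = 1.2),
               class = "jx_argument_error")
})
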