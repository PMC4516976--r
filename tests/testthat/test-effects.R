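.eff_fit <- local({
  fit <- NULL
  function() {
    if (is.null(fit)) fit <<- fit_transition(.models_dat(), tol = 1e-12)
    fit
  }
})

test_that("genotype and interaction contrasts carry the documented weights", {
  ge <- genotype_effect(.eff_fit(), 1, e = 280)
  expect_equal(ge$contrast, c(X = 1, Y1X = 1, EX = 280, Y1EX = 280))
  ge0 <- genotype_effect(.eff_fit(), 1, e = 0)
  expect_equal(ge0$contrast, c(X = 1, Y1X = 1, EX = 0, Y1EX = 0))
  expect_equal(genotype_effect(.eff_fit(), 0, e = 0)$contrast, c(X = 1, EX = 0))
  ie <- interaction_effect(.eff_fit(), 0, delta_e = 140)
  expect_equal(ie$contrast, c(EX = 140))
  ie1 <- interaction_effect(.eff_fit(), 1, delta_e = 1)
  expect_equal(ie1$contrast, c(EX = 1, Y1EX = 1))
  ## dichotomous algebra: effect in the exposed equals main + interaction
  g1 <- genotype_effect(.eff_fit(), 1, e = 1)
  expect_equal(g1$log_or,
               genotype_effect(.eff_fit(), 1, 0)$log_or + ie1$log_or,
               tolerance = 1e-12)
  expect_equal(ge$or, exp(ge$log_or))
  ## zero change -> null effect with zero variance
  ie0 <- interaction_effect(.eff_fit(), 0, delta_e = 0)
  expect_equal(ie0$log_or, 0); expect_equal(ie0$se, 0)
  expect_error(genotype_effect(.eff_fit(), 2, e = 0),
               class = "jx_contrast_error")
})

test_that("the contrast SE equals the genotype coefficient SE after recentering the exposure", {
  dat <- .models_dat()
  for (e_level in c(0.25, 1)) {
    dat_c <- dat; dat_c$E <- dat_c$E - e_level
    f_c <- fit_transition(dat_c, tol = 1e-12)
    for (s in 0:1) {
      eff <- genotype_effect(.eff_fit(), s, e_level)
      cf <- f_c$disease_fit
      ct <- if (s == 0) c(X = 1) else c(X = 1, Y1X = 1)
      cv <- setNames(numeric(length(cf$coefficients)),
                     names(cf$coefficients))
      cv[names(ct)] <- ct
      se_refit <- sqrt(drop(t(cv) %*% cf$robust_vcov %*% cv))
      expect_equal(eff$log_or, sum(cv * cf$coefficients), tolerance = 1e-7)
      expect_equal(eff$se, se_refit, tolerance = 1e-6)
    }
  }
})

test_that("Wald tests reduce to squared z-scores and match dense-algebra quadratic forms", {
  fit <- .eff_fit()
  ge <- genotype_effect(fit, 1, 1)
  w1 <- wald_test(fit, rbind(.contrast <- {
    cv <- setNames(numeric(9), names(fit$disease_fit$coefficients))
    cv[c("X", "Y1X", "EX", "Y1EX")] <- 1; cv
  }))
  expect_equal(w1$chi2, (ge$log_or / ge$se)^2, tolerance = 1e-10)
  expect_equal(w1$df, 1)
  ## 2-df test against explicit 2x2 inversion
  C <- matrix(0, 2, 9, dimnames = list(NULL, names(fit$disease_fit$coefficients)))
  C[1, c("X", "Y1X")] <- 1
  C[2, c("EX", "Y1EX")] <- 1
  w2 <- wald_test(fit, C)
  cb <- drop(C %*% fit$disease_fit$coefficients)
  V <- C %*% fit$disease_fit$robust_vcov %*% t(C)
  det2 <- V[1, 1] * V[2, 2] - V[1, 2]^2
  Vinv <- matrix(c(V[2, 2], -V[1, 2], -V[2, 1], V[1, 1]), 2) / det2
  expect_equal(w2$chi2, drop(t(cb) %*% Vinv %*% cb), tolerance = 1e-10)
  expect_equal(w2$df, 2)
  ## the conditional joint test is exactly that stacked 2-df Wald test
  jt <- conditional_joint_test(fit, 1)
  expect_equal(jt$chi2, w2$chi2, tolerance = 1e-12)
  expect_equal(jt$df, 2)
  ## dependent rows are rejected
  expect_error(wald_test(fit, rbind(C[1, ], 2 * C[1, ])),
               class = "jx_test_error")
})

test_that("the conditional joint test refuses continuous-exposure fits", {
  cfg <- .cached_cfg("transition2", "continuous")
  cfg$n_families <- 400
  dat <- simulate_dataset(cfg)
  ft <- fit_transition(dat)
  expect_error(conditional_joint_test(ft, 0), class = "jx_strategy_error")
  ## and the two-quartile strategy applies, with the documented alpha split
  cs <- continuous_strategy(ft)
  expect_equal(unique(cs$alpha_per_test), 0.05 / 4)
  expect_equal(nrow(cs), 4)                  # 2 strata x 2 levels
  fd <- fit_disease_only(dat)
  expect_equal(unique(continuous_strategy(fd)$alpha_per_test), 0.05 / 2)
  fp <- fit_polytomous(dat)
  expect_equal(unique(continuous_strategy(fp)$alpha_per_test), 0.05 / 6)
  expect_error(continuous_strategy(ft, q1 = 280, q3 = 140),
               class = "jx_argument_error")
  expect_error(continuous_strategy(ft, q1 = 200, q3 = 200),
               class = "jx_argument_error")
})

test_that("Bonferroni adjustment multiplies and caps p-values", {
  expect_equal(bonferroni_adjust(0.01, 2), 0.02)
  expect_equal(bonferroni_adjust(0.6, 3), 1.0)
  expect_equal(bonferroni_adjust(c(0.01, 0.6), 3), c(0.03, 1.0))
  expect_error(bonferroni_adjust(0.01, 0), class = "jx_argument_error")
  eff <- genotype_effect(.eff_fit(), 0, 1, m = 2)
  expect_equal(eff$p_adjusted, min(1, 2 * eff$p_raw))
})
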