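test_that("working-independence logistic GEE equals maximum likelihood on singleton clusters", {
  set.seed(1)
  n <- 400
  X <- cbind("(Intercept)" = 1, x1 = rnorm(n), x2 = rbinom(n, 1, 0.4))
  y <- rbinom(n, 1, plogis(-0.3 + 0.7 * X[, 2] - 0.5 * X[, 3]))
  fit <- fit_logistic_gee(clustered_design(y, X, seq_len(n)), tol = 1e-10)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$coefficients - oracle_logistic_ml(X, y))), 1e-6)
  expect_lt(max(abs(fit$coefficients - coef(glm(y ~ X[, 2] + X[, 3],
                                                family = binomial)))), 1e-6)
})

test_that("an intercept-only fit reproduces the log-odds of the observed counts", {
  y <- c(rep(1, 150), rep(0, 604))
  fit <- fit_logistic_gee(clustered_design(y, cbind("(Intercept)" = rep(1, 754)),
                                           rep_len(1:223, 754)), tol = 1e-10)
  expect_equal(unname(fit$coefficients), log(150 / 604), tolerance = 1e-8)
})

test_that("degenerate and rank-deficient designs are rejected", {
  n <- 50
  X <- cbind("(Intercept)" = 1, x = rnorm(n))
  expect_error(fit_logistic_gee(clustered_design(rep(0, n), X, seq_len(n))),
               class = "jx_separation_error")
  expect_error(clustered_design(rbinom(n, 1, 0.5),
                                cbind(X, x2 = 2 * X[, "x"]), seq_len(n)),
               class = "jx_rank_error")
  expect_error(fit_logistic_gee(clustered_design(rbinom(n, 1, .5), X,
                                                 rep(1, n))),
               class = "jx_variance_error")
})

test_that("the empirical sandwich matches a brute-force dense implementation and its scaling laws", {
  d <- fixture_clustered_binary(n_fam = 40)
  fit <- fit_logistic_gee(clustered_design(d$y, d$X, d$fam), tol = 1e-10)
  oracle <- oracle_logistic_sandwich(d$X, d$y, fit$coefficients, d$fam)
  expect_lt(max(abs(fit$robust_vcov - oracle)), 1e-10)

  ## permutation invariance
  set.seed(3)
  perm <- sample(length(d$y))
  fit_p <- fit_logistic_gee(clustered_design(d$y[perm], d$X[perm, ],
                                             d$fam[perm]), tol = 1e-10)
  expect_lt(max(abs(fit_p$robust_vcov - fit$robust_vcov)), 1e-10)

  ## duplicating every cluster halves the covariance
  fit_d <- fit_logistic_gee(clustered_design(
    c(d$y, d$y), rbind(d$X, d$X), c(d$fam, d$fam + max(d$fam))), tol = 1e-10)
  expect_equal(fit_d$robust_vcov, fit$robust_vcov / 2, tolerance = 1e-6)
})

test_that("singleton-cluster sandwich equals the heteroskedasticity-consistent ML covariance", {
  skip_if_not_installed("sandwich")
  set.seed(4)
  n <- 300
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.2 + 0.5 * x))
  fit <- fit_logistic_gee(clustered_design(y, cbind("(Intercept)" = 1, x = x),
                                           seq_len(n)), tol = 1e-10)
  g <- glm(y ~ x, family = binomial)
  expect_lt(max(abs(fit$robust_vcov - sandwich::vcovHC(g, type = "HC0"))), 1e-8)
})

test_that("polytomous estimating equations reduce to logistic for two categories and match multinomial ML", {
  set.seed(5)
  n <- 500
  X <- cbind("(Intercept)" = 1, x = rnorm(n))
  y <- rbinom(n, 1, plogis(-0.2 + 0.6 * X[, 2]))
  fb <- fit_logistic_gee(clustered_design(y, X, seq_len(n)), tol = 1e-10)
  fp <- fit_polytomous_gee(clustered_design(factor(y, levels = 0:1), X,
                                            seq_len(n)), tol = 1e-10)
  expect_lt(max(abs(unname(fp$coefficients) - unname(fb$coefficients))), 1e-6)

  ## three categories vs an independent BFGS ML oracle and nnet
  p3 <- exp(cbind(0, -0.4 + 0.5 * X[, 2], 0.2 - 0.7 * X[, 2]))
  p3 <- p3 / rowSums(p3)
  lab <- apply(p3, 1, function(p) sample(c("r", "a", "b"), 1, prob = p))
  lab <- factor(lab, levels = c("r", "a", "b"))
  f3 <- fit_polytomous_gee(clustered_design(lab, X, seq_len(n)), tol = 1e-12)
  Ymat <- model.matrix(~ lab - 1)[, paste0("lab", levels(lab))]
  expect_lt(max(abs(unname(f3$coefficients) -
                    oracle_multinomial_ml(X, Ymat))), 1e-6)
  skip_if_not_installed("nnet")
  m <- nnet::multinom(lab ~ X[, 2], trace = FALSE, reltol = 1e-14)
  expect_lt(max(abs(unname(f3$coefficients) - as.vector(t(coef(m))))), 1e-5)
})

test_that("polytomous robust covariance with singleton clusters equals the ML heteroskedasticity-consistent form", {
  set.seed(6)
  n <- 400
  X <- cbind("(Intercept)" = 1, x = rnorm(n))
  p3 <- exp(cbind(0, -0.3 + 0.4 * X[, 2], 0.1 - 0.5 * X[, 2]))
  p3 <- p3 / rowSums(p3)
  lab <- factor(apply(p3, 1, function(p) sample(3, 1, prob = p)), levels = 1:3)
  f3 <- fit_polytomous_gee(clustered_design(lab, X, seq_len(n)), tol = 1e-12)
  ## brute-force HC0: bread from the per-observation information, meat from
  ## per-observation score outer products, assembled with dense loops
  B <- matrix(0, 4, 4); M <- matrix(0, 4, 4)
  beta <- matrix(unname(f3$coefficients), 2, 2)
  for (i in seq_len(n)) {
    a <- exp(c(0, X[i, ] %*% beta))
    pr <- a / sum(a)
    yi <- as.integer(lab[i] == 2:3)
    si <- as.vector(outer(X[i, ], yi - pr[2:3]))
    M <- M + si %*% t(si)
    W <- diag(pr[2:3]) - pr[2:3] %*% t(pr[2:3])
    B <- B + kronecker(W, X[i, ] %*% t(X[i, ]))
  }
  ## kronecker gives category-major blocks in the same order as the fit
  hc0 <- solve(B) %*% M %*% solve(B)
  expect_lt(max(abs(unname(f3$robust_vcov) - hc0)), 1e-8)
})

test_that("empty categories are rejected", {
  X <- cbind("(Intercept)" = 1, x = rnorm(30))
  lab <- factor(rep(c("r", "a"), 15), levels = c("r", "a", "b"))
  expect_error(fit_polytomous_gee(clustered_design(lab, X, seq_len(30))),
               class = "jx_category_error")
})

test_that("relationship-specific working correlation with zero correlations equals independence", {
  d <- fixture_clustered_binary(n_fam = 50)
  des_ind <- clustered_design(d$y, d$X, d$fam)
  ## no pair information: all class correlations stay 0
  f_rel <- fit_logistic_gee(des_ind, "relationship", tol = 1e-10)
  f_ind <- fit_logistic_gee(des_ind, "independence", tol = 1e-10)
  expect_lt(max(abs(f_rel$coefficients - f_ind$coefficients)), 1e-8)
  expect_lt(max(abs(f_rel$robust_vcov - f_ind$robust_vcov)), 1e-8)
})

test_that("robust standard errors track the empirical replicate SD", {
  reps <- 400
  est <- se <- numeric(reps)
  for (r in seq_len(reps)) {
    d <- fixture_clustered_binary(n_fam = 100, fam_size = 4, seed = 1000 + r)
    fit <- fit_logistic_gee(clustered_design(d$y, d$X, d$fam))
    est[r] <- fit$coefficients["x1"]
    se[r] <- sqrt(fit$robust_vcov["x1", "x1"])
  }
  expect_lt(abs(mean(se) / sd(est) - 1), 0.10)
})
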