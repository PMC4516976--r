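#' Scenario configuration for the family simulator
#'
#' Defines one generating scenario: the joint model generating disease
#' (`Y2`) and endophenotype (`Y1`), the exposure type, the subject-specific
#' coefficients, the family random-effect standard deviations, the minor
#' allele frequency and the sample size.  Defaults emulate a family study of
#' metabolic syndrome (MetS, `Y2`) and abdominal obesity (`Y1`) with
#' physical activity as exposure: 223 families totalling about 754 adult
#' subjects, marginal prevalence of abdominal obesity 29.2%, of MetS 60.5%
#' given abdominal obesity and 3.2% without it (hence 19.9% overall).
#'
#' Three generating models are available, each a subject-specific (random
#' intercept per family and outcome equation) logistic structure:
#' \describe{
#'   \item{`transition1`}{`Y1` from a logistic model in exposure `E`,
#'     allele count `X` and age; `Y2` given `Y1` from a second logistic
#'     model; the gene-environment interaction is confined to subjects with
#'     the endophenotype (`Y1 = 1`).}
#'   \item{`transition2`}{as `transition1` but the interaction is confined
#'     to subjects without the endophenotype (`Y1 = 0`).}
#'   \item{`polytomous`}{the four categories `(Y1,Y2)` follow a
#'     baseline-category logit model; the genotype acts on MetS only among
#'     subjects with abdominal obesity, and the exposure is positively
#'     associated with both outcomes.}
#' }
#'
#' With a dichotomous exposure the subject-specific genotype log-OR in the
#' susceptible (exposed) group is 0.693 under the transition scenarios and
#' 1.39 under the polytomous scenario.  With a continuous exposure the
#' genotype log-OR at the third quartile (280 points) is -0.973 under the
#' transition scenarios (interaction -0.487 per interquartile range of 140
#' points) and +1.433 under the polytomous scenario (interaction +0.647 per
#' 140 points, main effect 0.139 at zero exposure).
#'
#' Intercept-type coefficients (`a0`, `g0`, `g4`, `b10`, `b20`, `b30`)
#' default to `NA` and are filled by [calibrate_intercepts()] so that the
#' marginal prevalences above are attained.
#'
#' @param generating_model One of `"transition1"`, `"transition2"`,
#'   `"polytomous"`.
#' @param exposure_kind `"dichotomous"` (marginal prevalence 0.50) or
#'   `"continuous"` (activity-score-like, population quartiles 140 and 280
#'   points, decreasing with age).
#' @param n_families Number of families (default 223).
#' @param maf Minor allele frequency of the causal variant (default 0.25).
#' @param coefficients Optional named list overriding any subject-specific
#'   coefficient: vectors `alpha` (`a0`..`a4`), `gamma` (`g0`..`g8`) for
#'   transition models, or matrix `beta` (rows `cat10`, `cat01`, `cat11`;
#'   columns `b0`, `bE`, `bX`, `bEX`, `bZ`) for the polytomous model.
#' @param random_sd Family random-intercept standard deviations, one per
#'   outcome equation (default 0.9 each).
#' @param exposure_sd Family effect scale of the exposure: latent-probit SD
#'   for the dichotomous case (default 0.6), log-scale SD for the
#'   continuous case (default 0.3).
#' @param exposure_age_slope Continuous exposure only: decrease of the
#'   log mean score per decade of age (default 0.1).
#' @param null_variant If `TRUE` (default), an additional unlinked variant
#'   with the same allele frequency and no phenotypic effect is simulated
#'   (column `X_null`) for type-I error studies.
#' @param targets Calibration targets, see [calibrate_intercepts()].
#' @param seed Integer seed; all randomness flows from it.
#'
#' @return An object of class `"scenario_config"`.
#' @export
scenario_config <- function(generating_model = c("transition1", "transition2",
                                                 "polytomous"),
                            exposure_kind = c("dichotomous", "continuous"),
                            n_families = 223L,
                            maf = 0.25,
                            coefficients = list(),
                            random_sd = NULL,
                            exposure_sd = NULL,
                            exposure_age_slope = 0.1,
                            null_variant = TRUE,
                            targets = NULL,
                            seed = 1L) {
  generating_model <- match.arg(generating_model)
  exposure_kind <- match.arg(exposure_kind)
  if (maf <= 0 || maf >= 1)
    jx_stop("maf must lie in (0, 1)", "jx_argument_error")
  if (n_families < 1)
    jx_stop("n_families must be >= 1", "jx_argument_error")
  co <- .default_coefficients(generating_model, exposure_kind)
  for (nm in names(coefficients)) {
    if (!nm %in% names(co))
      jx_stop(sprintf("coefficient block '%s' does not belong to model %s",
                      nm, generating_model), "jx_config_error")
    blk <- coefficients[[nm]]
    if (is.matrix(co[[nm]])) {
      co[[nm]][rownames(blk), colnames(blk)] <- blk
    } else {
      bad <- setdiff(names(blk), names(co[[nm]]))
      if (length(bad))
        jx_stop(sprintf("unknown coefficient(s) %s in block '%s'",
                        paste(bad, collapse = ", "), nm), "jx_config_error")
      co[[nm]][names(blk)] <- blk
    }
  }
  if (is.null(random_sd)) {
    random_sd <- if (generating_model == "polytomous")
      c(cat10 = 0.9, cat01 = 0.9, cat11 = 0.9) else c(y1 = 0.9, y2 = 0.9)
  }
  if (any(random_sd < 0)) jx_stop("random_sd must be >= 0", "jx_config_error")
  if (is.null(exposure_sd))
    exposure_sd <- if (exposure_kind == "dichotomous") 0.6 else 0.3
  if (is.null(targets)) {
    targets <- if (generating_model == "polytomous")
      c(cat10 = 87 / 754, cat01 = 17 / 754, cat11 = 133 / 754)
    else c(y1 = 0.292, y2_given_y1_0 = 0.032, y2_given_y1_1 = 0.605)
  }
  structure(list(generating_model = generating_model,
                 exposure_kind = exposure_kind,
                 n_families = as.integer(n_families), maf = maf,
                 coefficients = co, random_sd = random_sd,
                 exposure_sd = exposure_sd,
                 exposure_age_slope = exposure_age_slope,
                 null_variant = isTRUE(null_variant),
                 targets = targets, seed = as.integer(seed)),
            class = "scenario_config")
}

## subject-specific generating coefficients; interaction coefficients of the
## continuous scenarios are stored per exposure point
.default_coefficients <- function(model, exposure) {
  if (model %in% c("transition1", "transition2")) {
    if (exposure == "dichotomous") {
      alpha <- c(a0 = NA, a1 = -0.4, a2 = 0, a3 = 0, a4 = 0.3)
      gamma <- c(g0 = NA, g1 = -0.3, g2 = 0, g3 = 0, g4 = NA,
                 g5 = 0, g6 = 0, g7 = 0, g8 = 0.3)
      if (model == "transition1") gamma["g7"] <- log(2)          # 0.693
      else { gamma["g3"] <- log(2); gamma["g7"] <- -log(2) }
    } else {
      alpha <- c(a0 = NA, a1 = -0.3 / 140, a2 = 0, a3 = 0, a4 = 0.3)
      gamma <- c(g0 = NA, g1 = -0.3 / 140, g2 = 0, g3 = 0, g4 = NA,
                 g5 = 0, g6 = 0, g7 = 0, g8 = 0.3)
      if (model == "transition1") gamma["g7"] <- -0.487 / 140
      else { gamma["g3"] <- -0.487 / 140; gamma["g7"] <- 0.487 / 140 }
    }
    list(alpha = alpha, gamma = gamma)
  } else {
    beta <- matrix(0, 3, 5,
                   dimnames = list(c("cat10", "cat01", "cat11"),
                                   c("b0", "bE", "bX", "bEX", "bZ")))
    beta[, "b0"] <- NA
    beta[, "bZ"] <- 0.3
    if (exposure == "dichotomous") {
      beta[, "bE"] <- c(0.4, 0.4, 0.6)
      beta["cat11", "bEX"] <- 1.39
    } else {
      beta[, "bE"] <- c(0.3, 0.3, 0.45) / 140
      beta["cat11", "bX"] <- 0.139
      beta["cat11", "bEX"] <- 0.647 / 140
    }
    list(beta = beta)
  }
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("Scenario: %s model, %s exposure, %d families, MAF %.2f\n",
              x$generating_model, x$exposure_kind, x$n_families, x$maf))
  cal <- !anyNA(unlist(x$coefficients))
  cat(sprintf("intercepts %s; random-effect SDs: %s\n",
              if (cal) "calibrated" else "NOT calibrated",
              paste(sprintf("%s=%.2f", names(x$random_sd), x$random_sd),
                    collapse = ", ")))
  invisible(x)
}

## structure mix: nuclear families with 1-4 adult children dominate, with a
## small share of 3-generation extended families; weights give ~754 subjects
## in 223 families in expectation
.family_mix <- list(p_extended = 0.02,
                    children_probs = c(0.80, 0.15, 0.04, 0.01))

#' Generate family structures with ages
#'
#' Draws pedigrees from a mixture of two-generation nuclear families (two
#' founder parents plus 1-4 adult children) and three-generation extended
#' families (a founder couple, two married offspring and their children),
#' with mixture weights chosen so that 223 families comprise about 754
#' subjects in expectation.  Ages are drawn uniformly within
#' generation-specific adult bands spanning 18-79 years.
#'
#' @param n_families Number of families (>= 1).
#' @param seed Optional integer seed.
#' @return A list of [pedigree()] objects named by family id.
#' @export
generate_pedigrees <- function(n_families, seed = NULL) {
  if (n_families < 1) jx_stop("n_families must be >= 1", "jx_argument_error")
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n_families), function(f) {
    fam <- sprintf("F%04d", f)
    if (stats::runif(1) < .family_mix$p_extended)
      .gen_extended(fam)
    else
      .gen_nuclear(fam)
  })
}

.gen_nuclear <- function(fam) {
  k <- sample(1:4, 1, prob = .family_mix$children_probs)
  id <- c("1", "2", paste0("3", letters[seq_len(k)]))
  pedigree(fam,
           id = id,
           father_id = c(NA, NA, rep("1", k)),
           mother_id = c(NA, NA, rep("2", k)),
           sex = c(1L, 2L, sample(1:2, k, replace = TRUE)),
           age = c(stats::runif(2, 48, 79), stats::runif(k, 18, 50)))
}

.gen_extended <- function(fam) {
  k1 <- sample(1:2, 1); k2 <- sample(1:2, 1)
  sex_a <- sample(1:2, 2, replace = TRUE)
  id <- c("gf", "gm", "a1", "s1", "a2", "s2",
          paste0("c1", letters[seq_len(k1)]), paste0("c2", letters[seq_len(k2)]))
  father1 <- if (sex_a[1] == 1) "a1" else "s1"
  mother1 <- if (sex_a[1] == 1) "s1" else "a1"
  father2 <- if (sex_a[2] == 1) "a2" else "s2"
  mother2 <- if (sex_a[2] == 1) "s2" else "a2"
  pedigree(fam,
           id = id,
           father_id = c(NA, NA, "gf", NA, "gf", NA,
                         rep(father1, k1), rep(father2, k2)),
           mother_id = c(NA, NA, "gm", NA, "gm", NA,
                         rep(mother1, k1), rep(mother2, k2)),
           sex = c(1L, 2L, sex_a[1], 3L - sex_a[1], sex_a[2], 3L - sex_a[2],
                   sample(1:2, k1 + k2, replace = TRUE)),
           age = c(stats::runif(2, 68, 79), stats::runif(4, 45, 67),
                   stats::runif(k1 + k2, 18, 40)))
}

#' Drop genotypes through pedigrees
#'
#' Founders receive two independent alleles at the given frequency
#' (Hardy-Weinberg); each offspring receives one allele from each parent,
#' chosen uniformly, so genotypes are Mendelian-consistent by construction.
#'
#' @param peds List of [pedigree()] objects.
#' @param maf Allele frequency in `[0, 1]`.
#' @param seed Optional integer seed.
#' @return Integer vector of allele counts (0/1/2), one per subject, in the
#'   row order of the concatenated pedigrees.
#' @export
simulate_genotypes <- function(peds, maf, seed = NULL) {
  if (maf < 0 || maf > 1) jx_stop("maf must lie in [0, 1]", "jx_argument_error")
  if (!is.null(seed)) set.seed(seed)
  unlist(lapply(peds, function(ped) {
    n <- nrow(ped)
    depth <- .generation_depth(ped)
    ord <- order(depth)
    fa <- match(ped$father_id, ped$id)
    mo <- match(ped$mother_id, ped$id)
    ## store the two alleles separately for exact transmission
    al <- matrix(NA_integer_, n, 2)
    for (i in ord) {
      if (is.na(fa[i])) {
        al[i, ] <- stats::rbinom(2, 1, maf)
      } else {
        al[i, 1] <- al[fa[i], sample(2, 1)]
        al[i, 2] <- al[mo[i], sample(2, 1)]
      }
    }
    rowSums(al)
  }), use.names = FALSE)
}

## continuous exposure: E = scale * Gamma(shape) * exp(b_f - delta * Z),
## shape/scale calibrated so that population Q1/Q3 are ~140/280 points
## under the default family SD (0.3) and age slope (0.1/decade)
.cont_exposure_shape <- 7.312
.cont_exposure_scale <- 32.495

#' Simulate the environmental exposure
#'
#' Dichotomous: a shared family effect on a latent probit scale plus an
#' individual standard-normal deviate, thresholded at zero, giving marginal
#' prevalence 0.50 with familial clustering.  Continuous: a nonnegative
#' activity-score-like variable (15-min periods of moderate-to-vigorous
#' activity over 3 days) with population quartiles of about 140 and 280
#' points, a multiplicative family effect and a decreasing trend with age.
#'
#' @param peds List of [pedigree()] objects.
#' @param cfg A [scenario_config()].
#' @param seed Optional integer seed.
#' @return Numeric vector of exposures, one per subject.
#' @export
simulate_exposure <- function(peds, cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sizes <- vapply(peds, nrow, integer(1))
  fam_idx <- rep(seq_along(peds), sizes)
  n <- sum(sizes)
  if (cfg$exposure_kind == "dichotomous") {
    b <- stats::rnorm(length(peds), 0, cfg$exposure_sd)
    as.numeric(b[fam_idx] + stats::rnorm(n) > 0)
  } else if (cfg$exposure_kind == "continuous") {
    age <- unlist(lapply(peds, `[[`, "age"), use.names = FALSE)
    zc <- (age - 40) / 10
    b <- stats::rnorm(length(peds), 0, cfg$exposure_sd)
    .cont_exposure_scale * stats::rgamma(n, shape = .cont_exposure_shape) *
      exp(b[fam_idx] - cfg$exposure_age_slope * zc)
  } else jx_stop("unknown exposure kind", "jx_argument_error")
}

.age_z <- function(age) (age - 40) / 10

## linear predictors (without intercept-level random effects)
.lp_y1 <- function(co, E, X, Z)
  co$alpha["a0"] + co$alpha["a1"] * E + co$alpha["a2"] * X +
    co$alpha["a3"] * E * X + co$alpha["a4"] * Z

.lp_y2 <- function(co, Y1, E, X, Z) {
  g <- co$gamma
  g["g0"] + g["g1"] * E + g["g2"] * X + g["g3"] * E * X +
    g["g4"] * Y1 + g["g5"] * Y1 * E + g["g6"] * Y1 * X +
    g["g7"] * Y1 * E * X + g["g8"] * Z
}

.lp_poly <- function(co, E, X, Z) {
  b <- co$beta
  sapply(rownames(b), function(r)
    b[r, "b0"] + b[r, "bE"] * E + b[r, "bX"] * X +
      b[r, "bEX"] * E * X + b[r, "bZ"] * Z)
}

#' Simulate endophenotype and disease outcomes
#'
#' Transition scenarios: `Y1` is drawn from its logistic model plus a
#' family random intercept, then `Y2` from the conditional logistic model
#' given `Y1` plus a second, independent family random intercept.
#' Polytomous scenario: the four categories `(Y1,Y2)` are drawn from the
#' baseline-category model with one family random intercept per
#' non-reference category.
#'
#' @param peds List of [pedigree()] objects.
#' @param X Allele counts per subject ([simulate_genotypes()]).
#' @param E Exposures per subject ([simulate_exposure()]).
#' @param cfg A [scenario_config()] with calibrated (non-`NA`) intercepts.
#' @param seed Optional integer seed.
#' @return A list with binary vectors `Y1` and `Y2`.
#' @export
simulate_phenotypes <- function(peds, X, E, cfg, seed = NULL) {
  if (anyNA(unlist(cfg$coefficients)))
    jx_stop("scenario intercepts are NA; run calibrate_intercepts() first or set them explicitly",
            "jx_config_error")
  if (!is.null(seed)) set.seed(seed)
  sizes <- vapply(peds, nrow, integer(1))
  fam_idx <- rep(seq_along(peds), sizes)
  age <- unlist(lapply(peds, `[[`, "age"), use.names = FALSE)
  Z <- .age_z(age)
  n <- length(Z)
  stopifnot(length(X) == n, length(E) == n)
  co <- cfg$coefficients
  if (cfg$generating_model %in% c("transition1", "transition2")) {
    b1 <- stats::rnorm(length(peds), 0, cfg$random_sd["y1"])
    b2 <- stats::rnorm(length(peds), 0, cfg$random_sd["y2"])
    Y1 <- stats::rbinom(n, 1, .expit(.lp_y1(co, E, X, Z) + b1[fam_idx]))
    Y2 <- stats::rbinom(n, 1, .expit(.lp_y2(co, Y1, E, X, Z) + b2[fam_idx]))
  } else {
    B <- vapply(seq_len(3), function(k)
      stats::rnorm(length(peds), 0, cfg$random_sd[k]), numeric(length(peds)))
    Lp <- .lp_poly(co, E, X, Z) + B[fam_idx, , drop = FALSE]
    Pm <- cbind(1, exp(Lp))
    Pm <- Pm / rowSums(Pm)
    cat_draw <- apply(Pm, 1, function(p) sample.int(4, 1, prob = p))
    Y1 <- as.integer(cat_draw %in% c(2L, 4L))   # cat10 or cat11
    Y2 <- as.integer(cat_draw %in% c(3L, 4L))   # cat01 or cat11
  }
  list(Y1 = Y1, Y2 = Y2)
}

#' Simulate a complete family dataset under a scenario
#'
#' Runs pedigree generation, gene dropping (causal and, optionally, an
#' unlinked null variant), exposure simulation and phenotype simulation,
#' all seeded from `cfg$seed`; fixed seed gives a bit-identical dataset.
#' Intercepts are calibrated on the fly if still `NA` (pass a calibrated
#' config to avoid repeating that step).
#'
#' @param cfg A [scenario_config()].
#' @return A data frame (the family dataset) with columns `family_id`,
#'   `subject_id`, `father_id`, `mother_id`, `sex`, `age`, `X`, `E`, `Y1`,
#'   `Y2` and, if requested, `X_null`; the pedigree list is attached as
#'   attribute `"pedigrees"`.
#' @export
simulate_dataset <- function(cfg) {
  if (anyNA(unlist(cfg$coefficients)))
    cfg <- calibrate_intercepts(cfg)
  set.seed(cfg$seed)
  peds <- generate_pedigrees(cfg$n_families)
  X <- simulate_genotypes(peds, cfg$maf)
  Xn <- if (cfg$null_variant) simulate_genotypes(peds, cfg$maf)
  E <- simulate_exposure(peds, cfg)
  ph <- simulate_phenotypes(peds, X, E, cfg)
  dat <- data.frame(
    family_id = rep(vapply(peds, attr, "", which = "family_id"),
                    vapply(peds, nrow, integer(1))),
    subject_id = unlist(lapply(peds, `[[`, "id"), use.names = FALSE),
    father_id = unlist(lapply(peds, `[[`, "father_id"), use.names = FALSE),
    mother_id = unlist(lapply(peds, `[[`, "mother_id"), use.names = FALSE),
    sex = unlist(lapply(peds, `[[`, "sex"), use.names = FALSE),
    age = unlist(lapply(peds, `[[`, "age"), use.names = FALSE),
    X = X, E = E, Y1 = ph$Y1, Y2 = ph$Y2,
    stringsAsFactors = FALSE)
  if (cfg$null_variant) dat$X_null <- Xn
  attr(dat, "pedigrees") <- peds
  attr(dat, "scenario") <- cfg
  dat
}

## Gauss-Hermite marginalization: E_b[expit(lp + b)], b ~ N(0, sd^2)
.gh <- function(m = 21) {
  gh <- pracma::gaussHermite(m)
  list(x = gh$x, w = gh$w / sqrt(pi))
}

#' Marginal success probability of a random-intercept logistic model
#'
#' Computes `E[expit(lp + b)]` with `b ~ N(0, sd^2)` by Gauss-Hermite
#' quadrature, vectorized over linear predictors.
#'
#' @param lp Numeric vector of subject-specific linear predictors.
#' @param sd Random-intercept standard deviation.
#' @param m Number of quadrature nodes (default 21).
#' @return Vector of marginal probabilities.
#' @export
marginal_prevalence <- function(lp, sd, m = 21) {
  if (sd == 0) return(.expit(lp))
  gh <- .gh(m)
  shift <- sqrt(2) * sd * gh$x
  drop(.expit(outer(lp, shift, "+")) %*% gh$w)
}

## marginal category probabilities of the polytomous generating model with
## independent random intercepts (product Gauss-Hermite)
.marginal_poly <- function(Lp, sds, m = 5) {
  gh <- .gh(m)
  n <- nrow(Lp)
  P <- matrix(0, n, 4)
  E1 <- exp(Lp[, 1]); E2 <- exp(Lp[, 2]); E3 <- exp(Lp[, 3])
  for (i1 in seq_len(m)) for (i2 in seq_len(m)) for (i3 in seq_len(m)) {
    wgt <- gh$w[i1] * gh$w[i2] * gh$w[i3]
    f1 <- E1 * exp(sqrt(2) * sds[1] * gh$x[i1])
    f2 <- E2 * exp(sqrt(2) * sds[2] * gh$x[i2])
    f3 <- E3 * exp(sqrt(2) * sds[3] * gh$x[i3])
    den <- 1 + f1 + f2 + f3
    P[, 1] <- P[, 1] + wgt / den
    P[, 2] <- P[, 2] + wgt * f1 / den
    P[, 3] <- P[, 3] + wgt * f2 / den
    P[, 4] <- P[, 4] + wgt * f3 / den
  }
  colnames(P) <- c("cat00", "cat10", "cat01", "cat11")
  P
}

## simulate a covariate sample (ages, genotypes, exposures) for calibration
## and population-averaged oracles; deterministic given seed
.covariate_sample <- function(cfg, n_subjects, seed) {
  set.seed(seed)
  n_fam <- ceiling(n_subjects / 3.38)
  peds <- generate_pedigrees(n_fam)
  X <- simulate_genotypes(peds, cfg$maf)
  E <- simulate_exposure(peds, cfg)
  age <- unlist(lapply(peds, `[[`, "age"), use.names = FALSE)
  list(X = X, E = E, Z = .age_z(age),
       fam = rep(seq_along(peds), vapply(peds, nrow, integer(1))))
}

#' Calibrate scenario intercepts to target prevalences
#'
#' Solves, by one-dimensional root finding on a large simulated covariate
#' sample with exact (Gauss-Hermite) marginalization over the family random
#' effects, for the intercept-type coefficients so that the marginal
#' prevalences match their targets.  Transition models: `a0` for the
#' endophenotype prevalence, `g0` for the disease prevalence without
#' endophenotype impairment, `g4` for the disease prevalence with
#' impairment.  Polytomous model: the three category intercepts are cycled
#' until all category prevalences match.
#'
#' @param cfg A [scenario_config()].
#' @param targets Named prevalence targets in `(0, 1)`; defaults to
#'   `cfg$targets` (Table-style marginals: endophenotype 29.2%, disease
#'   60.5% / 3.2% with/without impairment, or the four-category analogues).
#' @param n Covariate sample size for the calibration (default 200000;
#'   20000 for the polytomous model whose three-dimensional quadrature is
#'   heavier).
#' @param tol Prevalence tolerance (default 0.005, checked by simulation in
#'   the test suite).
#' @return The config with intercepts filled in.
#' @export
calibrate_intercepts <- function(cfg, targets = NULL, n = NULL, tol = 0.005) {
  if (is.null(targets)) targets <- cfg$targets
  if (any(targets <= 0 | targets >= 1))
    jx_stop("targets must lie in (0, 1)", "jx_argument_error")
  seed <- bitwXor(cfg$seed, 193939L) %% 2147483647L
  co <- cfg$coefficients
  if (cfg$generating_model %in% c("transition1", "transition2")) {
    if (is.null(n)) n <- 200000L
    cov <- .covariate_sample(cfg, n, seed)
    fill <- function(v, nm, val) { v[nm] <- val; v }
    ## endophenotype marginal
    f_a0 <- function(a0) {
      co$alpha <- fill(co$alpha, "a0", a0)
      mean(marginal_prevalence(.lp_y1(co, cov$E, cov$X, cov$Z),
                               cfg$random_sd["y1"])) - targets["y1"]
    }
    co$alpha["a0"] <- stats::uniroot(f_a0, c(-15, 15), tol = 1e-8)$root
    p1 <- marginal_prevalence(.lp_y1(co, cov$E, cov$X, cov$Z),
                              cfg$random_sd["y1"])
    ## disease given Y1 = 0 (depends on g0 only, among intercept terms)
    co$gamma["g4"] <- 0
    f_g0 <- function(g0) {
      co$gamma <- fill(co$gamma, "g0", g0)
      p2 <- marginal_prevalence(.lp_y2(co, 0, cov$E, cov$X, cov$Z),
                                cfg$random_sd["y2"])
      sum(p2 * (1 - p1)) / sum(1 - p1) - targets["y2_given_y1_0"]
    }
    co$gamma["g0"] <- stats::uniroot(f_g0, c(-15, 15), tol = 1e-8)$root
    ## disease given Y1 = 1 (g4 on top of the calibrated g0)
    f_g4 <- function(g4) {
      co$gamma <- fill(co$gamma, "g4", g4)
      p2 <- marginal_prevalence(.lp_y2(co, 1, cov$E, cov$X, cov$Z),
                                cfg$random_sd["y2"])
      sum(p2 * p1) / sum(p1) - targets["y2_given_y1_1"]
    }
    co$gamma["g4"] <- stats::uniroot(f_g4, c(-5, 20), tol = 1e-8)$root
  } else {
    if (is.null(n)) n <- 20000L
    cov <- .covariate_sample(cfg, n, seed)
    cats <- c("cat10", "cat01", "cat11")
    if (anyNA(co$beta[, "b0"])) co$beta[, "b0"] <- -2
    for (cycle in seq_len(8)) {
      max_gap <- 0
      for (k in seq_len(3)) {
        f_b0 <- function(b0) {
          co$beta[cats[k], "b0"] <- b0
          P <- .marginal_poly(.lp_poly(co, cov$E, cov$X, cov$Z),
                              cfg$random_sd)
          mean(P[, k + 1]) - targets[cats[k]]
        }
        co$beta[cats[k], "b0"] <- stats::uniroot(f_b0, c(-15, 10),
                                                 tol = 1e-7)$root
      }
      P <- .marginal_poly(.lp_poly(co, cov$E, cov$X, cov$Z), cfg$random_sd)
      max_gap <- max(abs(colMeans(P)[2:4] - targets[cats]))
      if (max_gap < tol / 10) break
    }
    if (max_gap > tol)
      jx_stop(sprintf("polytomous intercept calibration did not reach targets (max gap %.4f)",
                      max_gap), "jx_convergence_error")
  }
  cfg$coefficients <- co
  cfg
}

#' Population-averaged (marginal) coefficients of a scenario
#'
#' Numerical-integration oracle for the attenuated, population-averaged
#' coefficients that a GEE analysis estimates: marginal outcome
#' probabilities are computed for a large simulated covariate sample by
#' Gauss-Hermite quadrature over the family random effects, and the
#' correctly specified analysis model is then fitted to those exact
#' fractional probabilities by weighted estimating equations.  Also returns
#' the population-averaged coefficients of the disease-only model (the
#' logistic projection of the marginal disease probability on exposure,
#' genotype, their product and age).
#'
#' @param cfg A calibrated [scenario_config()].
#' @param n Covariate sample size (default 100000; the larger the sample,
#'   the smaller the Monte-Carlo error in the covariate distribution).
#' @param seed Seed of the covariate sample (default derived from
#'   `cfg$seed`).
#' @return A list with components `alpha`, `gamma` (transition scenarios)
#'   or `beta` (polytomous scenario), and `eta` (disease-only), each a
#'   named vector on the analysis-model term scale.
#' @export
pa_coefficients <- function(cfg, n = 100000L, seed = NULL) {
  if (anyNA(unlist(cfg$coefficients)))
    jx_stop("calibrate the scenario before computing population-averaged coefficients",
            "jx_config_error")
  if (is.null(seed)) seed <- bitwXor(cfg$seed, 777551L) %% 2147483647L
  cov <- .covariate_sample(cfg, n, seed)
  co <- cfg$coefficients
  XD <- cbind("(Intercept)" = 1, E = cov$E, X = cov$X, EX = cov$E * cov$X,
              Z = cov$Z)
  fit_frac <- function(p, X, w = NULL) {
    d <- clustered_design(p, X, cluster_id = seq_len(nrow(X)), weights = w)
    fit_logistic_gee(d, "independence", tol = 1e-10)$coefficients
  }
  out <- list()
  if (cfg$generating_model %in% c("transition1", "transition2")) {
    p1 <- marginal_prevalence(.lp_y1(co, cov$E, cov$X, cov$Z),
                              cfg$random_sd["y1"])
    out$alpha <- fit_frac(p1, XD)
    p2_0 <- marginal_prevalence(.lp_y2(co, 0, cov$E, cov$X, cov$Z),
                                cfg$random_sd["y2"])
    p2_1 <- marginal_prevalence(.lp_y2(co, 1, cov$E, cov$X, cov$Z),
                                cfg$random_sd["y2"])
    ## stack both endophenotype strata, weighted by their probabilities
    XD2 <- function(y1)
      cbind(XD, Y1 = y1, Y1E = y1 * cov$E, Y1X = y1 * cov$X,
            Y1EX = y1 * cov$E * cov$X)
    Xg <- rbind(XD2(0), XD2(1))[, c(1:4, 6:9, 5)]  # term order of the fit
    out$gamma <- fit_frac(c(p2_0, p2_1), Xg, w = c(1 - p1, p1))
    pm <- (1 - p1) * p2_0 + p1 * p2_1
    out$eta <- fit_frac(pm, XD)
  } else {
    P <- .marginal_poly(.lp_poly(co, cov$E, cov$X, cov$Z), cfg$random_sd)
    d <- clustered_design(P, XD, cluster_id = seq_len(nrow(XD)))
    pf <- fit_polytomous_gee(d, tol = 1e-10)
    out$beta <- pf$coefficients
    out$eta <- fit_frac(P[, "cat01"] + P[, "cat11"], XD)
  }
  out
}
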