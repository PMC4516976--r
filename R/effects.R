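## Effect derivation: every reported effect is a linear combination c'b of
## fitted coefficients, with variance c' S c taken from the empirical
## (sandwich) covariance S.

## underlying jx_fit + model kind of any of the three analysis fits
.fit_core <- function(fit) {
  if (inherits(fit, "transition_fit"))
    list(core = fit$disease_fit, kind = "transition", exposure = fit$exposure)
  else if (inherits(fit, "polytomous_fit"))
    list(core = fit$fit, kind = "polytomous", exposure = fit$exposure,
         trichotomous = fit$trichotomous)
  else if (inherits(fit, "disease_only_fit"))
    list(core = fit$fit, kind = "disease_only", exposure = fit$exposure)
  else if (inherits(fit, "jx_fit"))
    list(core = fit, kind = if (fit$kind == "polytomous") "polytomous"
         else "disease_only", exposure = NULL)
  else jx_stop("not a fitted model object", "jx_argument_error")
}

## number of equations tested under the model's Bonferroni strategy
.n_equations <- function(fc) {
  switch(fc$kind,
         transition = 2L,
         polytomous = length(fc$core$categories),
         disease_only = 1L)
}

## named contrast -> full-length weight vector aligned with coefficients
.contrast_vector <- function(core, contrast) {
  cn <- names(core$coefficients)
  bad <- setdiff(names(contrast), cn)
  if (length(bad))
    jx_stop(sprintf("contrast names not among model terms: %s",
                    paste(bad, collapse = ", ")),
            "jx_contrast_error")
  cv <- stats::setNames(numeric(length(cn)), cn)
  cv[names(contrast)] <- contrast
  cv
}

.make_effect <- function(core, contrast, label, level = 0.95, m = 1L) {
  cv <- .contrast_vector(core, contrast)
  est <- sum(cv * core$coefficients)
  se <- sqrt(drop(t(cv) %*% core$robust_vcov %*% cv))
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- if (se > 0) stats::pchisq((est / se)^2, df = 1, lower.tail = FALSE)
       else as.numeric(est == 0)
  structure(list(label = label, contrast = contrast, log_or = est, se = se,
                 or = exp(est),
                 ci_low = exp(est - z * se), ci_high = exp(est + z * se),
                 p_raw = p, p_adjusted = min(1, m * p),
                 n_tests_correction = as.integer(m), level = level),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("%s: log-OR %.4f (robust SE %.4f), OR %.2f [%.2f, %.2f], p %.4g (adjusted %.4g, m = %d)\n",
              x$label, x$log_or, x$se, x$or, x$ci_low, x$ci_high,
              x$p_raw, x$p_adjusted, x$n_tests_correction))
  invisible(x)
}

## contrast weights of the genotype effect at exposure e
.genotype_contrast <- function(fc, stratum_or_category, e) {
  if (fc$kind == "transition") {
    s <- .check_stratum(stratum_or_category)
    if (s == 0) c(X = 1, EX = e) else c(X = 1, Y1X = 1, EX = e, Y1EX = e)
  } else if (fc$kind == "polytomous") {
    cc <- .check_category(fc, stratum_or_category)
    stats::setNames(c(1, e), paste0(cc, ":", c("X", "EX")))
  } else c(X = 1, EX = e)
}

.interaction_contrast <- function(fc, stratum_or_category, delta_e) {
  if (fc$kind == "transition") {
    s <- .check_stratum(stratum_or_category)
    if (s == 0) c(EX = delta_e) else c(EX = delta_e, Y1EX = delta_e)
  } else if (fc$kind == "polytomous") {
    cc <- .check_category(fc, stratum_or_category)
    stats::setNames(delta_e, paste0(cc, ":EX"))
  } else c(EX = delta_e)
}

.check_stratum <- function(s) {
  if (!length(s) == 1 || !s %in% c(0, 1))
    jx_stop("transition-model stratum must be 0 (no endophenotype impairment) or 1",
            "jx_contrast_error")
  as.integer(s)
}

.check_category <- function(fc, cc) {
  if (!length(cc) == 1 || !cc %in% fc$core$categories)
    jx_stop(sprintf("unknown polytomous category '%s' (available: %s)",
                    cc, paste(fc$core$categories, collapse = ", ")),
            "jx_contrast_error")
  cc
}

#' Genotype effect at an exposure level
#'
#' The log-OR per allele at absolute exposure level `e`, derived as a
#' linear combination of coefficients of a fitted model.  Transition model,
#' stratum without endophenotype impairment: `X + e * EX`; with impairment:
#' `X + Y1X + e * (EX + Y1EX)`.  Polytomous model, category `k`:
#' `k:X + e * k:EX`.  Disease-only: `X + e * EX`.
#'
#' @param fit A fit from [fit_transition()], [fit_polytomous()] or
#'   [fit_disease_only()].
#' @param stratum_or_category Endophenotype stratum (0/1) for transition
#'   fits; category label (`"cat10"`, `"cat01"`, `"cat11"`) for polytomous
#'   fits; ignored for disease-only fits.
#' @param e Absolute exposure level (e.g. 1 for the exposed group of a
#'   dichotomous exposure, or an activity-score quartile).
#' @param level Confidence level (default 0.95).
#' @param m Bonferroni multiplier applied to the p-value (default 1).
#' @return An `"effect_estimate"`: log-OR, robust SE, OR with CI, raw and
#'   adjusted p-value.
#' @export
genotype_effect <- function(fit, stratum_or_category = NULL, e,
                            level = 0.95, m = 1L) {
  fc <- .fit_core(fit)
  ct <- .genotype_contrast(fc, stratum_or_category, e)
  lab <- sprintf("genotype effect at E = %g%s", e,
                 if (fc$kind == "transition")
                   sprintf(" (stratum Y1 = %d)", .check_stratum(stratum_or_category))
                 else if (fc$kind == "polytomous")
                   sprintf(" (%s)", stratum_or_category) else "")
  .make_effect(fc$core, ct, lab, level, m)
}

#' Gene-environment interaction effect
#'
#' The change in genotype log-OR for a `delta_e` change in exposure:
#' `delta_e * EX` (plus `delta_e * Y1EX` in the impaired stratum of the
#' transition model).  For a dichotomous exposure use `delta_e = 1`; for a
#' continuous exposure a change equal to the interquartile range (e.g. 140
#' points) is conventional.
#'
#' @inheritParams genotype_effect
#' @param delta_e Exposure change over which the interaction is reported.
#' @return An `"effect_estimate"`.
#' @export
interaction_effect <- function(fit, stratum_or_category = NULL, delta_e,
                               level = 0.95, m = 1L) {
  fc <- .fit_core(fit)
  ct <- .interaction_contrast(fc, stratum_or_category, delta_e)
  lab <- sprintf("interaction effect per %g exposure units%s", delta_e,
                 if (fc$kind == "transition")
                   sprintf(" (stratum Y1 = %d)", .check_stratum(stratum_or_category))
                 else if (fc$kind == "polytomous")
                   sprintf(" (%s)", stratum_or_category) else "")
  .make_effect(fc$core, ct, lab, level, m)
}

#' Wald test of linear hypotheses on model coefficients
#'
#' Tests `C b = 0` via the quadratic form
#' `(C b)' (C S C')^{-1} (C b)` with the empirical covariance `S`,
#' referred to a chi-square distribution with `q = nrow(C)` degrees of
#' freedom.
#'
#' @param fit A fitted model (any of the three analysis fits or a raw
#'   `jx_fit`).
#' @param contrast_matrix Numeric matrix with `q` linearly independent
#'   rows; columns either span all coefficients or carry a subset of
#'   coefficient names.
#' @return List with `chi2`, `df`, `p`.
#' @export
wald_test <- function(fit, contrast_matrix) {
  fc <- .fit_core(fit)
  core <- fc$core
  C <- rbind(contrast_matrix)
  if (!is.null(colnames(C)) && ncol(C) < length(core$coefficients)) {
    Cf <- matrix(0, nrow(C), length(core$coefficients),
                 dimnames = list(NULL, names(core$coefficients)))
    bad <- setdiff(colnames(C), names(core$coefficients))
    if (length(bad))
      jx_stop(sprintf("contrast names not among model terms: %s",
                      paste(bad, collapse = ", ")), "jx_contrast_error")
    Cf[, colnames(C)] <- C
    C <- Cf
  }
  if (qr(C)$rank < nrow(C))
    jx_stop("contrast rows are linearly dependent", "jx_test_error")
  cb <- drop(C %*% core$coefficients)
  V <- C %*% core$robust_vcov %*% t(C)
  Vi <- tryCatch(solve(V), error = function(e)
    jx_stop("singular covariance of the contrast", "jx_test_error"))
  chi2 <- drop(t(cb) %*% Vi %*% cb)
  q <- nrow(C)
  list(chi2 = chi2, df = q,
       p = stats::pchisq(chi2, df = q, lower.tail = FALSE))
}

#' Joint 2-df conditional test of genotype and interaction effects
#'
#' For a dichotomous exposure: the simultaneous Wald test of the genotype
#' effect in unexposed subjects and the gene-environment interaction
#' effect (2 degrees of freedom).  In the impaired stratum of the
#' transition model this is the joint test of `X + Y1X` and `EX + Y1EX`.
#' Not defined for a continuous exposure, where the two-quartile strategy
#' of [continuous_strategy()] applies instead.
#'
#' @inheritParams genotype_effect
#' @return List with `chi2`, `df = 2`, `p`.
#' @export
conditional_joint_test <- function(fit, stratum_or_category = NULL) {
  fc <- .fit_core(fit)
  if (!is.null(fc$exposure) && length(unique(fc$exposure)) > 2)
    jx_stop("the conditional joint test requires a dichotomous exposure; use continuous_strategy() with two exposure levels instead",
            "jx_strategy_error")
  c1 <- .contrast_vector(fc$core,
                         .genotype_contrast(fc, stratum_or_category, 0))
  c2 <- .contrast_vector(fc$core,
                         .interaction_contrast(fc, stratum_or_category, 1))
  wald_test(fit, rbind(c1, c2))
}

#' Bonferroni adjustment
#'
#' @param p_values Numeric vector of raw p-values.
#' @param m Number of tests (>= 1).
#' @return `pmin(1, m * p_values)`.
#' @export
bonferroni_adjust <- function(p_values, m) {
  if (m < 1) jx_stop("m must be >= 1", "jx_argument_error")
  pmin(1, m * p_values)
}

#' Two-quartile testing strategy for a continuous exposure
#'
#' Estimates and tests the genotype effect at a low and a high exposure
#' level (by default the first and third quartiles of the analyzed
#' exposure), in every stratum or category of the model, with a Bonferroni
#' correction for the `2 * (number of equations)` tests performed: per-test
#' alpha 0.05/4 for the transition model, 0.05/6 for the four-category
#' polytomous model (0.05/4 trichotomous), 0.05/2 for the disease-only
#' model.
#'
#' @inheritParams genotype_effect
#' @param q1,q3 Low and high exposure levels, `q1 < q3`; default to the
#'   empirical quartiles of the exposure in the analyzed data.
#' @param alpha Familywise significance level (default 0.05).
#' @return A data frame with one row per (stratum/category, level):
#'   columns `stratum`, `exposure_level`, `log_or`, `se`, `or`, `ci_low`,
#'   `ci_high`, `p_raw`, `p_adjusted`, `alpha_per_test`, `significant`.
#' @export
continuous_strategy <- function(fit, q1 = NULL, q3 = NULL, alpha = 0.05,
                                level = 0.95) {
  fc <- .fit_core(fit)
  if (is.null(q1) || is.null(q3)) {
    if (is.null(fc$exposure))
      jx_stop("supply q1 and q3 explicitly for a raw fit", "jx_argument_error")
    qq <- stats::quantile(fc$exposure, c(0.25, 0.75), names = FALSE)
    if (is.null(q1)) q1 <- qq[1]
    if (is.null(q3)) q3 <- qq[2]
  }
  if (q1 >= q3)
    jx_stop("q1 must be strictly below q3", "jx_argument_error")
  strata <- switch(fc$kind,
                   transition = c(0, 1),
                   polytomous = fc$core$categories,
                   disease_only = list(NULL))
  m <- 2L * .n_equations(fc)
  rows <- list()
  for (s in strata) for (e in c(q1, q3)) {
    eff <- genotype_effect(fit, s, e, level = level, m = m)
    rows[[length(rows) + 1L]] <- data.frame(
      stratum = if (is.null(s)) "overall" else as.character(s),
      exposure_level = e, log_or = eff$log_or, se = eff$se, or = eff$or,
      ci_low = eff$ci_low, ci_high = eff$ci_high,
      p_raw = eff$p_raw, p_adjusted = eff$p_adjusted,
      alpha_per_test = alpha / m,
      significant = eff$p_raw < alpha / m,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "m") <- m
  out
}

#' Effects table of a fitted model
#'
#' Genotype effects at chosen exposure levels for every stratum or
#' category, formatted as an OR / CI / adjusted-p table.
#'
#' @inheritParams genotype_effect
#' @param exposure_levels Exposure levels at which the genotype effect is
#'   reported.
#' @param m Bonferroni multiplier; defaults to
#'   `length(exposure_levels) * number of equations`.
#' @param stratum_labels Optional labels replacing the stratum/category
#'   codes (e.g. `c("MetS (normal WC)", "MetS (elevated WC)")`).
#' @return Data frame with one row per (stratum, level).
#' @export
effects_table <- function(fit, exposure_levels, m = NULL,
                          stratum_labels = NULL, level = 0.95) {
  fc <- .fit_core(fit)
  strata <- switch(fc$kind,
                   transition = c(0, 1),
                   polytomous = fc$core$categories,
                   disease_only = list(NULL))
  if (is.null(m)) m <- length(exposure_levels) * .n_equations(fc)
  rows <- list()
  for (k in seq_along(strata)) {
    s <- strata[[k]]
    lab <- if (!is.null(stratum_labels)) stratum_labels[k]
           else if (is.null(s)) "overall" else as.character(s)
    for (e in exposure_levels) {
      eff <- genotype_effect(fit, s, e, level = level, m = m)
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = lab, exposure_level = e,
        or = eff$or, ci_low = eff$ci_low, ci_high = eff$ci_high,
        p_raw = eff$p_raw, p_adjusted = eff$p_adjusted,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
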