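#' Replicate-level simulation study
#'
#' Simulates many family datasets under one scenario, analyzes each with
#' the requested analysis models, derives the genotype and interaction
#' effects and their tests under the model-specific Bonferroni strategy,
#' and aggregates mean estimate, mean robust SE, empirical SD, power (or
#' type-I error, for the unlinked null variant), and 95% CI coverage of
#' the true population-averaged effects.
#'
#' Testing strategy: with a dichotomous exposure, the genotype test is the
#' joint 2-df conditional test (genotype effect in unexposed subjects plus
#' interaction) and the interaction test a 1-df Wald test, each at
#' `alpha / m` with `m` the number of model equations (2 for transition, 3
#' for four-category polytomous, 1 for disease-only).  With a continuous
#' exposure, the genotype effect is tested at the third quartile at
#' `alpha / (2 m)` (Bonferroni over two exposure levels), the interaction
#' over an interquartile-range change at `alpha / m`.
#'
#' Replicate seeds are pre-drawn from the master seed, so the summary is
#' reproducible and independent of execution order.  Replicates where a fit
#' fails or does not converge are excluded from the statistics and counted;
#' a warning is emitted when exclusions exceed 1%.
#'
#' @param cfg A [scenario_config()]; calibrated automatically if needed.
#' @param analyses Character subset of `c("transition", "polytomous",
#'   "disease_only")`.
#' @param n_reps Number of replicates (>= 1).
#' @param workcorr Working correlation for the logistic fits.
#' @param alpha Familywise significance level (default 0.05).
#' @param seed Master seed (defaults to `cfg$seed`).
#' @param truth Optional list as returned by [pa_coefficients()]; computed
#'   with `pa_n` covariate draws when `NULL` and `coverage = TRUE`.
#' @param pa_n Covariate sample size for the population-averaged oracle.
#' @param coverage Evaluate CI coverage against the population-averaged
#'   truth (correctly specified and disease-only analyses only)?
#' @param quartiles Optional `c(q1, q3)` exposure levels for the
#'   continuous strategy; defaults to 140 and 280.
#' @param delta_e Interaction reporting change for a continuous exposure
#'   (default 140 points).
#' @return A `"study_summary"` data frame: one row per (analysis, stratum,
#'   effect, variant) with columns `mean_estimate`, `mean_se`,
#'   `empirical_sd`, `power`, `coverage`, `truth`, `alpha_used`, `n_reps`,
#'   `n_converged`.
#' @export
run_study <- function(cfg,
                      analyses = c("transition", "polytomous", "disease_only"),
                      n_reps = 1000L,
                      workcorr = "independence",
                      alpha = 0.05,
                      seed = NULL,
                      truth = NULL,
                      pa_n = 50000L,
                      coverage = TRUE,
                      quartiles = c(140, 280),
                      delta_e = 140) {
  if (n_reps < 1) jx_stop("n_reps must be >= 1", "jx_argument_error")
  analyses <- match.arg(analyses, several.ok = TRUE)
  if (anyNA(unlist(cfg$coefficients))) cfg <- calibrate_intercepts(cfg)
  if (is.null(seed)) seed <- cfg$seed
  if (coverage && is.null(truth)) truth <- pa_coefficients(cfg, n = pa_n)
  dichot <- cfg$exposure_kind == "dichotomous"

  set.seed(seed)
  rep_seeds <- sample.int(2147483646L, n_reps)
  rows <- vector("list", n_reps)
  n_failed <- stats::setNames(integer(length(analyses)), analyses)
  for (r in seq_len(n_reps)) {
    cfg_r <- cfg; cfg_r$seed <- rep_seeds[r]
    dat <- simulate_dataset(cfg_r)
    rep_rows <- list()
    for (an in analyses) {
      for (variant in c("causal", if (cfg$null_variant) "null")) {
        gcol <- if (variant == "causal") "X" else "X_null"
        fit <- tryCatch(suppressMessages(switch(an,
          transition = fit_transition(dat, workcorr, genotype_col = gcol),
          polytomous = fit_polytomous(dat, genotype_col = gcol),
          disease_only = fit_disease_only(dat, workcorr,
                                          genotype_col = gcol))),
          error = function(e) NULL)
        ok <- !is.null(fit) && .study_converged(fit)
        if (!ok) {
          if (variant == "causal") n_failed[an] <- n_failed[an] + 1L
          next
        }
        rep_rows[[length(rep_rows) + 1L]] <-
          .replicate_effects(fit, an, variant, dichot, quartiles, delta_e,
                             alpha, rep = r)
      }
    }
    rows[[r]] <- do.call(rbind, rep_rows)
  }
  long <- do.call(rbind, rows)
  if (any(n_failed > 0.01 * n_reps))
    warning(sprintf("more than 1%% of replicates excluded for: %s",
                    paste(names(n_failed)[n_failed > 0.01 * n_reps],
                          collapse = ", ")))
  summarize_study(long, cfg, truth = truth, n_reps = n_reps)
}

.study_converged <- function(fit) {
  if (inherits(fit, "transition_fit"))
    fit$endophenotype_fit$converged && fit$disease_fit$converged
  else fit$fit$converged
}

## per-replicate long rows: one per (stratum, effect) with estimate, SE,
## CI and the strategy-specific rejection indicator
.replicate_effects <- function(fit, analysis, variant, dichot, quartiles,
                               delta_e, alpha, rep) {
  fc <- .fit_core(fit)
  m <- .n_equations(fc)
  strata <- switch(fc$kind,
                   transition = c(0, 1),
                   polytomous = fc$core$categories,
                   disease_only = list(NULL))
  e_geno <- if (dichot) 1 else quartiles[2]
  d_e <- if (dichot) 1 else delta_e
  out <- list()
  for (s in strata) {
    ge <- genotype_effect(fit, s, e_geno)
    ie <- interaction_effect(fit, s, d_e)
    if (dichot) {
      jt <- conditional_joint_test(fit, s)
      rej_g <- jt$p < alpha / m
      alpha_g <- alpha / m
    } else {
      rej_g <- ge$p_raw < alpha / (2 * m)
      alpha_g <- alpha / (2 * m)
    }
    rej_i <- ie$p_raw < alpha / m
    slab <- if (is.null(s)) "overall" else as.character(s)
    out[[length(out) + 1L]] <- data.frame(
      rep = rep, analysis = analysis, variant = variant, stratum = slab,
      effect = c("genotype", "interaction"),
      estimate = c(ge$log_or, ie$log_or),
      se = c(ge$se, ie$se),
      ci_low = log(c(ge$ci_low, ie$ci_low)),
      ci_high = log(c(ge$ci_high, ie$ci_high)),
      reject = c(rej_g, rej_i),
      alpha_used = c(alpha_g, alpha / m),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

## true population-averaged value of each summarized effect, or NA when the
## analysis model is misspecified for the scenario
.truth_value <- function(truth, cfg, analysis, stratum, effect, e_geno, d_e,
                         variant = "causal") {
  if (is.null(truth)) return(NA_real_)
  if (variant == "null") return(0)    # unlinked variant: no effect

  correct <- switch(cfg$generating_model,
                    transition1 = "transition", transition2 = "transition",
                    polytomous = "polytomous")
  cf <- if (analysis == "transition" && correct == "transition") truth$gamma
        else if (analysis == "polytomous" && correct == "polytomous") truth$beta
        else if (analysis == "disease_only") truth$eta
        else return(NA_real_)
  fake <- list(core = list(coefficients = cf,
                           categories = c("cat10", "cat01", "cat11")),
               kind = analysis)
  if (analysis == "disease_only") fake$kind <- "disease_only"
  s_arg <- if (analysis == "transition") as.numeric(stratum)
           else if (analysis == "polytomous") stratum else NULL
  ct <- if (effect == "genotype") .genotype_contrast(fake, s_arg, e_geno)
        else .interaction_contrast(fake, s_arg, d_e)
  cv <- stats::setNames(numeric(length(cf)), names(cf))
  cv[names(ct)] <- ct
  sum(cv * cf)
}

#' Summarize replicate results into a study table
#'
#' @param long Long per-replicate data frame as produced internally by
#'   [run_study()] (columns `rep`, `analysis`, `variant`, `stratum`,
#'   `effect`, `estimate`, `se`, `ci_low`, `ci_high`, `reject`,
#'   `alpha_used`).
#' @param cfg The scenario configuration (for truth lookup).
#' @param truth Population-averaged truth ([pa_coefficients()]) or `NULL`.
#' @param n_reps Number of replicates attempted.
#' @return A `"study_summary"` data frame.
#' @export
summarize_study <- function(long, cfg, truth = NULL, n_reps = NA_integer_) {
  if (is.null(long) || !nrow(long))
    jx_stop("no converged replicates to summarize", "jx_summary_error")
  dichot <- cfg$exposure_kind == "dichotomous"
  e_geno <- if (dichot) 1 else 280
  d_e <- if (dichot) 1 else 140
  key <- interaction(long$analysis, long$variant, long$stratum, long$effect,
                     drop = TRUE)
  out <- lapply(split(long, key), function(d) {
    tv <- .truth_value(truth, cfg, d$analysis[1], d$stratum[1], d$effect[1],
                       e_geno, d_e, d$variant[1])
    cov <- if (is.na(tv)) NA_real_
           else mean(d$ci_low <= tv & tv <= d$ci_high)
    data.frame(analysis = d$analysis[1], variant = d$variant[1],
               stratum = d$stratum[1], effect = d$effect[1],
               mean_estimate = mean(d$estimate), mean_se = mean(d$se),
               empirical_sd = stats::sd(d$estimate),
               power = mean(d$reject), coverage = cov, truth = tv,
               alpha_used = d$alpha_used[1],
               n_reps = n_reps, n_converged = nrow(d),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$analysis, out$variant, out$stratum, out$effect), ]
  rownames(out) <- NULL
  class(out) <- c("study_summary", "data.frame")
  out
}

#' @export
print.study_summary <- function(x, ...) {
  cat("Simulation study summary (power = type-I error for the null variant)\n")
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, 4)
  print(y, row.names = FALSE)
  invisible(x)
}
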