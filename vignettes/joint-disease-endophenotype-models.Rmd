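---
title: "Joint disease-endophenotype models with gene-environment interaction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint disease-endophenotype models with gene-environment interaction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Motivation

Genetic variants detected by association studies typically show small
marginal effects on complex diseases.  A variant may nonetheless act
strongly in a subgroup defined by two modifiers at once: the level of an
environmental exposure, and the status of an intermediate heritable trait
(an *endophenotype*) related to the disease.  The motivating setting is the
metabolic syndrome (MetS) as disease endpoint, abdominal obesity as a
dichotomous endophenotype, and a quantitative physical-activity score as
exposure, in a family sample.  `jointGxE` implements joint models of the
disease and the endophenotype as functions of allele count, exposure and
age, estimated at the population level from family data, together with the
effect-derivation and testing machinery needed to report genotype effects
*at chosen exposure levels* inside each endophenotype stratum, and a
simulator plus replicate harness to characterize the estimators.

## Models

Write $Y_1$ for the endophenotype (1 = impaired), $Y_2$ for the disease,
$X \in \{0,1,2\}$ for the allele count, $E$ for the exposure and $Z$ for
the age covariate.  Three analysis models are provided.

**Transition model.**  Two chained logistic regressions: first the
endophenotype,
$$\mathrm{logit}\,P(Y_1 = 1 \mid E, X, Z) =
  \alpha_0 + \alpha_1 E + \alpha_2 X + \alpha_3 EX + \alpha_4 Z,$$
then the disease conditional on the endophenotype, with $Y_1$ allowed to
modify every effect:
$$\mathrm{logit}\,P(Y_2 = 1 \mid Y_1, E, X, Z) =
  \gamma_0 + \gamma_1 E + \gamma_2 X + \gamma_3 EX + \gamma_4 Y_1 +
  \gamma_5 Y_1 E + \gamma_6 Y_1 X + \gamma_7 Y_1 EX + \gamma_8 Z.$$
In the stratum without impairment the gene-environment interaction is
$\gamma_3$ and the genotype effect at exposure $e$ is
$\gamma_2 + \gamma_3 e$; with impairment they are $\gamma_3 + \gamma_7$
and $\gamma_2 + \gamma_6 + (\gamma_3 + \gamma_7)e$.  All are log
odds-ratios.

**Polytomous model.**  The four combinations of $(Y_1, Y_2)$ form a
nominal outcome modeled by baseline-category logits against the doubly
unaffected reference, one coefficient block
$(\beta_{k0}, \beta_{k1}, \beta_{k2}, \beta_{k3}, \beta_{k4})$ per
non-reference category $k$; a *trichotomous* variant drops subjects with
impairment but no disease.  Genotype effects at exposure $e$ are
$\beta_{k2} + \beta_{k3} e$ per category.

**Disease-only model.**  The standard logistic model of $Y_2$ on
$E, X, EX, Z$, ignoring the endophenotype; it serves as the comparison
baseline that joint modeling is meant to improve on.

## Estimation

Families are the clusters.  Coefficients solve generalized estimating
equations; inference uses the empirical (sandwich) covariance built from
cluster-level scores, which is consistent under arbitrary within-family
dependence regardless of the working correlation.  Two working structures
are available for the logistic fits: *independence*, under which point
estimates coincide with ordinary logistic maximum likelihood, and
*relationship-specific*, with one scalar correlation per relative-pair
class (spouse, parent-offspring, sibling, avuncular,
grandparent-grandchild, first cousin) estimated between scoring iterations
by moment averaging of Pearson-residual products within each class.  Pairs
outside the six classes (including half-siblings) get working correlation
zero.  A working matrix that fails positive definiteness is shrunk toward
independence by scaling its off-diagonal entries by the largest factor
restoring a minimum eigenvalue of $10^{-6}$.  The polytomous model is
fitted under working independence only — its estimating equations are then
exactly the multinomial logistic score equations, combined with the
cluster-level sandwich — which avoids local-odds-ratio machinery for the
nominal response.

Numerical choices: Fisher scoring with step-halving on the
estimating-function norm; convergence when the largest absolute
coefficient change falls below `tol` (default `1e-8`, at most 100
iterations); rank of the design checked up front; a fit whose linear
predictor exceeds 30 in absolute value is flagged for possible separation.
No small-sample correction is applied to the sandwich, matching the plain
empirical estimator; consequences at small cluster counts are discussed
under Limitations.

## Effects and testing strategy

Every reported effect is a linear combination $c'\hat\beta$ with variance
$c'\hat\Sigma c$ from the robust covariance, so its standard error equals
the one obtained by refitting with the exposure recentered at the level of
interest (a property the test suite checks to $10^{-6}$).  Wald tests use
the chi-square reference.  With a dichotomous exposure, the genotype test
is the joint 2-df *conditional* test of the genotype effect in unexposed
subjects together with the interaction effect; with a continuous exposure
that test is undefined (the genotype main effect refers to exposure zero),
so the strategy tests the genotype effect at two representative levels —
by default the first and third exposure quartiles — with a Bonferroni
factor of 2.  Bonferroni corrections multiply across model equations: 2
strata for the transition model, 3 (or 2) categories for the (tri- or)
four-category polytomous model, 1 for disease-only.  That gives per-test
levels $0.05/2$, $0.05/3$, $0.05$ for interaction or joint tests, and
$0.05/4$, $0.05/6$, $0.05/2$ for two-level genotype tests under a
continuous exposure.  Adjusted p-values ($\min(1, m\,p)$) are reported
alongside the per-test thresholds.

## The simulator

`scenario_config()` + `simulate_dataset()` generate family data under three
subject-specific (random-intercept) generating models: the interaction
confined to subjects *with* impairment (`transition1`), confined to
subjects *without* impairment (`transition2`), or a four-category
baseline-logit model in which the genotype acts on disease only among
impaired subjects and the exposure is positively associated with both
outcomes (`polytomous`).  Defaults emulate the motivating family study:

* **Families.** 223 families, about 754 adult subjects in expectation: a
  mixture of two-generation nuclear families (two founders plus 1–4
  children, probabilities 0.80/0.15/0.04/0.01) and 2% three-generation
  extended families (a founder couple, two married offspring, their
  children).  The exact structure mix of the motivating cohort is not
  published; the mixture was chosen once to reproduce the published family
  and subject counts and is configurable.
* **Ages.** Uniform within generation-specific adult bands spanning 18–79
  years (the age range of the national survey the MetS prevalence is
  referenced to); age enters every linear predictor as $(age-40)/10$, so
  intercepts and plotted odds refer to age 40.
* **Genotypes.** Founders draw two alleles at frequency 0.25 (a common-variant
  default; the true value is study-specific and configurable) under
  Hardy-Weinberg; offspring receive one uniformly chosen allele per parent,
  so Mendelian consistency holds by construction.  An optional second,
  unlinked variant with the same frequency and no effect supports type-I
  error studies.
* **Exposure.** Dichotomous: family probit intercept (SD 0.6) plus an
  individual normal deviate thresholded at zero — marginal prevalence 0.50
  by symmetry, with familial clustering.  Continuous: a
  gamma-distributed activity-like score with multiplicative family effect
  (log-SD 0.3) and a decline of 10% per decade of age; shape 7.312 and
  scale 32.495 were solved once so the population quartiles are 140 and
  280 score points.
* **Effect sizes.** Subject-specific genotype log-OR of $\log 2 = 0.693$
  in the susceptible group for the dichotomous transition scenarios
  (zero genotype effect in unexposed subjects); for continuous exposure,
  a genotype log-OR of $-0.973$ at the third quartile with interaction
  $-0.487$ per interquartile range (hence a zero main effect at $E=0$);
  the polytomous scenario uses $1.39$ (dichotomous) or main effect $0.139$
  with interaction $0.647$ per 140 points (continuous) in the
  doubly-affected category.
* **Random effects.** One family-level normal intercept per outcome
  equation, SD 0.9, independent across equations; this produces
  population-averaged effects attenuated by roughly 15% relative to the
  subject-specific values, the order of attenuation visible in the
  motivating study's simulations.  Kinship-structured polygenic effects
  are deliberately not the default (the kinship machinery is available in
  the pedigree module).
* **Calibration.** Intercept-type coefficients are solved by
  one-dimensional root finding so that marginal prevalences match the
  published table: endophenotype impairment 29.2%, disease 60.5% given
  impairment and 3.2% without (hence 19.9% overall), or the four-category
  analogues.  The marginal prevalence under a candidate intercept is
  computed exactly (21-node Gauss-Hermite over the random intercept; a
  5-node product rule over the three polytomous intercepts) on a large
  simulated covariate sample — 200,000 subjects by default, 20,000 for the
  polytomous model where the three-dimensional quadrature dominates.

What the simulator does *not* emulate: ascertainment or outcome-dependent
family sampling, sex-specific effects, missing data, inbreeding or loops,
linkage disequilibrium between variants, and measurement error in the
activity score.  Passing simulation checks therefore demonstrates the
estimators' behavior under clean random sampling of families, not
robustness to those features of real cohorts.

## Population-averaged truth

GEE estimates under a logistic link are population-averaged and hence
attenuated relative to the subject-specific generating coefficients
whenever the random-effect SD is positive.  The reference values used for
bias and coverage are therefore *not* the generating coefficients but the
population-averaged projection computed by `pa_coefficients()`: marginal
outcome probabilities obtained by Gauss-Hermite integration on a large
covariate sample, followed by a weighted (fractional-response) fit of the
analysis model to those exact probabilities.  For the disease-only model
the same construction defines the logistic projection that ignoring the
endophenotype converges to.

## The replicate study harness

`run_study()` simulates, fits every requested analysis model for the
causal and the null variant, derives effects and tests under the strategy
above, and aggregates mean estimate, mean robust SE, empirical SD,
rejection rate (power, or type-I error for the null variant) and 95% CI
coverage of the population-averaged truth, over converged replicates only
(counted, with a warning when exclusions exceed 1%).  Replicate seeds are
pre-drawn from the master seed, so results are reproducible and
independent of execution order.  The test suite exercises the harness at
scaled-down sizes chosen to keep the full check under a few minutes of
serial compute: 500 replicates, with 223 families (the motivating cohort
size) where the transition model's sparse stratum needs support and 50
families for the disease-only type-I error check; the large-sample
recovery check uses a single dataset of about 50,000 subjects, and
population-averaged truths use 30,000–100,000 covariate draws.

## Design decisions in the open

* **Relative-pair precedence.** In looped pedigrees a pair can satisfy
  several definitions; classification picks the closest genetic
  relationship (parent-offspring > sibling > grandparent-grandchild >
  avuncular > first-cousin > spouse).  Spouses are identified by a common
  offspring; marriage links are not stored.
* **Sparse-stratum behavior.** Disease without endophenotype impairment
  has prevalence 3.2%, so the corresponding transition-model stratum is
  thin: at 50 families the 9-parameter disease equation frequently fails
  to converge (such replicates are excluded and counted), and at 223
  families its robust SE slightly understates the empirical SD, giving
  coverage just below nominal in that stratum while the well-supported
  stratum is nominal.  This mirrors the liberal behavior reported for that
  stratum in the motivating study and is why coverage claims are made for
  the susceptible stratum.
* **Working-correlation estimation scale.** The per-class correlations are
  moment averages of Pearson-residual products (divisor $N_c - p$), the
  standard GEE recipe; estimating them on the linear-predictor scale was
  considered and rejected as nonstandard.
* **Continuous-exposure interaction storage.** Interaction coefficients
  are stored per exposure point and reported per 100 or 140 points at the
  effect-derivation layer, keeping design matrices in raw score units.
* **Quartile defaults.** `continuous_strategy()` defaults to the empirical
  quartiles of the analyzed exposure (simulation scenarios fix 140/280 by
  construction; observed cohorts will differ), with explicit overrides.
* **Command-line interface.** A thin wrapper
  (`inst/cli/jointgxe.R`) around `cli_main()` exposes `simulate`, `fit`
  and `study`; all logic stays in exported functions so scripted use needs
  no CLI.

## Limitations

The sandwich covariance is first-order: with few clusters (tens of
families) Wald tests are mildly liberal and CIs slightly narrow, and no
degrees-of-freedom correction is applied by default.  The polytomous model
is fitted under working independence only.  Ordinal (cumulative-logit)
responses, gene-gene models, dominance coding, ascertainment corrections
and mixed-model (subject-specific) estimation are out of scope; the
within-family score test that complements the population-level Wald tests
in the motivating work is provided by its own literature and not
reimplemented here.
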