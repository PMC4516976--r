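## Design-matrix builders for the three analysis models.  Term names are the
## package's stable vocabulary:
##   endophenotype equation:  (Intercept), E, X, EX, Z
##   disease (transition) eq: (Intercept), E, X, EX, Y1, Y1E, Y1X, Y1EX, Z
##   polytomous blocks:       <category>:(Intercept), :E, :X, :EX, :Z
##   disease-only:            (Intercept), E, X, EX, Z
## Z is age entered as (age - 40) / 10 so that intercepts refer to age 40.

.base_design <- function(dat, genotype_col = "X") {
  X <- dat[[genotype_col]]
  cbind("(Intercept)" = 1, E = dat$E, X = X, EX = dat$E * X,
        Z = .age_z(dat$age))
}

.transition_design <- function(dat, genotype_col = "X") {
  B <- .base_design(dat, genotype_col)
  cbind(B[, c("(Intercept)", "E", "X", "EX"), drop = FALSE],
        Y1 = dat$Y1, Y1E = dat$Y1 * dat$E, Y1X = dat$Y1 * B[, "X"],
        Y1EX = dat$Y1 * B[, "EX"], Z = B[, "Z"])
}

## complete cases on the analysis variables, with a logged count
.complete_cases <- function(dat, genotype_col, need_y1 = TRUE) {
  vars <- c(genotype_col, "E", "Y2", "age", if (need_y1) "Y1")
  keep <- stats::complete.cases(dat[, vars])
  if (any(!keep))
    message(sprintf("dropping %d of %d subjects with missing analysis variables",
                    sum(!keep), nrow(dat)))
  dat[keep, , drop = FALSE]
}

## relationship classes of within-family pairs as global row indices
.dataset_pair_classes <- function(dat, peds = attr(dat, "pedigrees")) {
  if (is.null(peds)) peds <- .peds_from_dataset(dat)
  out <- vector("list", length(peds))
  for (k in seq_along(peds)) {
    ped <- peds[[k]]
    fam <- attr(ped, "family_id")
    rows <- which(dat$family_id == fam)
    if (length(rows) < 2) next
    sub <- dat$subject_id[rows]
    pr <- relationship_pairs(ped)
    if (!nrow(pr)) next
    i1 <- rows[match(pr$id1, sub)]
    i2 <- rows[match(pr$id2, sub)]
    ok <- !is.na(i1) & !is.na(i2)     # pairs with both members analyzed
    out[[k]] <- data.frame(id1 = i1[ok], id2 = i2[ok],
                           class = pr$class[ok], stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

## rebuild pedigree objects from the dataset's parent columns
.peds_from_dataset <- function(dat) {
  lapply(split(dat, dat$family_id), function(d)
    pedigree(d$family_id[1], d$subject_id, d$father_id, d$mother_id,
             d$sex, d$age))
}

#' Fit the transition (endophenotype-conditional) model
#'
#' Two chained logistic GEE fits with the family as cluster: the
#' endophenotype `Y1` on exposure, allele count, their product and age; and
#' the disease `Y2` on the same terms plus `Y1` and its interactions with
#' every predictor, so that genotype and exposure effects may differ between
#' the endophenotype strata.
#'
#' @param dat Family dataset ([simulate_dataset()] or
#'   [read_family_table()]).
#' @param workcorr `"independence"` (default) or `"relationship"`.
#' @param genotype_col Genotype column to analyze (default `"X"`; use
#'   `"X_null"` for the unlinked null variant).
#' @param tol,max_iter Passed to [fit_logistic_gee()].
#' @return An object of class `"transition_fit"`: list with `jx_fit`
#'   components `endophenotype_fit` and `disease_fit`.
#' @export
fit_transition <- function(dat, workcorr = "independence",
                           genotype_col = "X", tol = 1e-8, max_iter = 100L) {
  dat <- .complete_cases(dat, genotype_col)
  for (s in 0:1) {
    sub <- dat$Y2[dat$Y1 == s]
    if (!length(sub) || length(unique(sub)) < 2)
      jx_stop(sprintf("endophenotype stratum Y1 = %d has no variation in disease status", s),
              "jx_stratum_error")
  }
  pc <- if (.as_workcorr(workcorr)$kind == "relationship")
    .dataset_pair_classes(dat) else NULL
  d1 <- clustered_design(dat$Y1, .base_design(dat, genotype_col),
                         dat$family_id, pair_classes = pc)
  f1 <- fit_logistic_gee(d1, workcorr, tol = tol, max_iter = max_iter)
  d2 <- clustered_design(dat$Y2, .transition_design(dat, genotype_col),
                         dat$family_id, pair_classes = pc)
  f2 <- fit_logistic_gee(d2, workcorr, tol = tol, max_iter = max_iter)
  structure(list(endophenotype_fit = f1, disease_fit = f2,
                 n_obs = nrow(dat), genotype_col = genotype_col,
                 exposure = dat$E),
            class = "transition_fit")
}

#' Fit the polytomous (baseline-category) model
#'
#' Four-category baseline-category logit GEE fit of the `(Y1, Y2)`
#' combinations against the doubly-unaffected reference `(0, 0)`, under
#' working independence with family-level sandwich covariance.  With
#' `trichotomous = TRUE`, subjects with endophenotype impairment but no
#' disease (`Y1 = 1, Y2 = 0`) are excluded and only the remaining two
#' non-reference categories are modeled.
#'
#' @inheritParams fit_transition
#' @param trichotomous Drop the `(1, 0)` category (default `FALSE`).
#' @return An object of class `"polytomous_fit"` wrapping a `jx_fit` with
#'   blocks named `cat10`, `cat01`, `cat11` (minus `cat10` when
#'   trichotomous).
#' @export
fit_polytomous <- function(dat, trichotomous = FALSE, genotype_col = "X",
                           tol = 1e-8, max_iter = 100L) {
  dat <- .complete_cases(dat, genotype_col)
  cat_lab <- ifelse(dat$Y1 == 0 & dat$Y2 == 0, "cat00",
             ifelse(dat$Y1 == 1 & dat$Y2 == 0, "cat10",
             ifelse(dat$Y1 == 0 & dat$Y2 == 1, "cat01", "cat11")))
  if (trichotomous) {
    keep <- cat_lab != "cat10"
    dat <- dat[keep, , drop = FALSE]
    cat_lab <- cat_lab[keep]
    lev <- c("cat00", "cat01", "cat11")
  } else lev <- c("cat00", "cat10", "cat01", "cat11")
  missing_cat <- setdiff(lev, unique(cat_lab))
  if (length(missing_cat))
    jx_stop(sprintf("phenotype category(ies) without observations: %s%s",
                    paste(missing_cat, collapse = ", "),
                    if (!trichotomous && all(missing_cat == "cat10"))
                      " (a trichotomous fit would succeed)" else ""),
            "jx_category_error")
  d <- clustered_design(factor(cat_lab, levels = lev),
                        .base_design(dat, genotype_col), dat$family_id)
  fit <- fit_polytomous_gee(d, tol = tol, max_iter = max_iter)
  structure(list(fit = fit, trichotomous = trichotomous,
                 n_obs = nrow(dat), genotype_col = genotype_col,
                 exposure = dat$E),
            class = "polytomous_fit")
}

#' Fit the standard disease-only logistic model
#'
#' Logistic GEE of the disease `Y2` on exposure, allele count, their
#' product and age, ignoring the endophenotype.
#'
#' @inheritParams fit_transition
#' @return An object of class `"disease_only_fit"` wrapping a `jx_fit`.
#' @export
fit_disease_only <- function(dat, workcorr = "independence",
                             genotype_col = "X", tol = 1e-8,
                             max_iter = 100L) {
  dat <- .complete_cases(dat, genotype_col, need_y1 = FALSE)
  pc <- if (.as_workcorr(workcorr)$kind == "relationship")
    .dataset_pair_classes(dat) else NULL
  d <- clustered_design(dat$Y2, .base_design(dat, genotype_col),
                        dat$family_id, pair_classes = pc)
  fit <- fit_logistic_gee(d, workcorr, tol = tol, max_iter = max_iter)
  structure(list(fit = fit, n_obs = nrow(dat),
                 genotype_col = genotype_col, exposure = dat$E),
            class = "disease_only_fit")
}

#' @export
print.transition_fit <- function(x, ...) {
  cat("Transition model fit\n== Endophenotype equation (Y1) ==\n")
  print(x$endophenotype_fit)
  cat("== Disease equation (Y2 | Y1) ==\n")
  print(x$disease_fit)
  invisible(x)
}

#' @export
print.polytomous_fit <- function(x, ...) {
  cat(sprintf("%s polytomous model fit (reference cat00)\n",
              if (x$trichotomous) "Trichotomous" else "Four-category"))
  print(x$fit)
  invisible(x)
}

#' @export
print.disease_only_fit <- function(x, ...) {
  cat("Disease-only logistic model fit\n")
  print(x$fit)
  invisible(x)
}
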