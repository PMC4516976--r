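#' Bundle a clustered regression design
#'
#' Container passed to the estimating-equation solvers: a response, a design
#' matrix with named columns, a cluster (family) identifier per row, and —
#' for the relationship-specific working correlation — the relationship
#' class of every within-cluster pair.
#'
#' @param response Binary 0/1 vector (logistic), values in `[0, 1]` are
#'   accepted as fractional responses for weighted marginal fits; or, for
#'   the polytomous solver, a factor/character of category labels, or an
#'   n-by-K matrix of category weights.
#' @param design_matrix Numeric matrix, n rows, named columns, full column
#'   rank.
#' @param cluster_id Vector of length n identifying the cluster of each row.
#' @param pair_classes Optional data frame with columns `id1`, `id2`,
#'   `class` of within-cluster pairs (see [relationship_pairs()]), where
#'   `id1`/`id2` are row indices into the design, or `NULL`.
#' @param weights Optional nonnegative prior weights (default 1).
#'
#' @return An object of class `"clustered_design"`.
#' @export
clustered_design <- function(response, design_matrix, cluster_id,
                             pair_classes = NULL, weights = NULL) {
  X <- as.matrix(design_matrix)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("V", seq_len(ncol(X)))
  n <- nrow(X)
  if (is.matrix(response)) {
    stopifnot(nrow(response) == n)
  } else stopifnot(length(response) == n)
  stopifnot(length(cluster_id) == n)
  if (is.null(weights)) weights <- rep(1, n)
  qr_X <- qr(X)
  if (qr_X$rank < ncol(X))
    jx_stop(sprintf("design matrix is rank deficient (rank %d < %d columns); offending columns include: %s",
                    qr_X$rank, ncol(X),
                    paste(colnames(X)[-qr_X$pivot[seq_len(qr_X$rank)]],
                          collapse = ", ")),
            "jx_rank_error")
  if (ncol(X) >= n)
    jx_stop("more design columns than observations", "jx_rank_error")
  structure(list(response = response, design_matrix = X,
                 cluster_id = as.character(cluster_id),
                 pair_classes = pair_classes, weights = weights),
            class = "clustered_design")
}

#' Working correlation specification
#'
#' @param kind `"independence"` or `"relationship"` (one scalar correlation
#'   per relative-pair class, estimated by moment averaging of
#'   Pearson-residual products between iterations).
#' @param classes Character vector of pair classes that receive their own
#'   correlation; pairs outside these classes get working correlation 0.
#' @return An object of class `"working_correlation"`.
#' @export
working_correlation <- function(kind = c("independence", "relationship"),
                                classes = c("spouse", "parent-offspring",
                                            "sibling", "avuncular",
                                            "grandparent-grandchild",
                                            "first-cousin")) {
  kind <- match.arg(kind)
  structure(list(kind = kind, classes = classes),
            class = "working_correlation")
}

.as_workcorr <- function(workcorr) {
  if (inherits(workcorr, "working_correlation")) return(workcorr)
  if (is.character(workcorr) && length(workcorr) == 1)
    return(working_correlation(match.arg(workcorr,
                                         c("independence", "relationship"))))
  jx_stop("workcorr must be 'independence', 'relationship' or a working_correlation object",
          "jx_argument_error")
}

.expit <- function(x) 1 / (1 + exp(-x))

#' Fit a logistic model to clustered data by generalized estimating equations
#'
#' Solves the logistic estimating equations by Fisher scoring with
#' step-halving.  Under working independence the point estimates coincide
#' with ordinary logistic maximum likelihood; the empirical (sandwich)
#' covariance aggregates scores at the cluster level and is consistent under
#' arbitrary within-cluster dependence.  Under the relationship-specific
#' working correlation one scalar correlation per relative-pair class is
#' re-estimated between scoring iterations by moment averaging of
#' Pearson-residual products; working matrices that fail positive
#' definiteness are shrunk toward independence.
#'
#' @param design A [clustered_design()] with binary (or fractional)
#'   response.
#' @param workcorr `"independence"` (default), `"relationship"` or a
#'   [working_correlation()].
#' @param tol Convergence tolerance on the maximum absolute coefficient
#'   change (default 1e-8).
#' @param max_iter Maximum Fisher-scoring iterations (default 100).
#'
#' @return An object of class `"jx_fit"`: list with `coefficients`,
#'   `robust_vcov`, `naive_vcov`, `fitted`, `linear_predictor`,
#'   `n_obs`, `n_clusters`, `iterations`, `converged`, `separation`,
#'   `working_correlations` (named, when relationship-specific), `kind =
#'   "logistic"`.
#' @export
fit_logistic_gee <- function(design, workcorr = "independence",
                             tol = 1e-8, max_iter = 100L) {
  wc <- .as_workcorr(workcorr)
  y <- design$response
  X <- design$design_matrix
  w <- design$weights
  if (is.matrix(y)) jx_stop("logistic GEE needs a vector response",
                            "jx_argument_error")
  if (any(y < 0 | y > 1)) jx_stop("binary response must lie in [0, 1]",
                                  "jx_argument_error")
  cl <- design$cluster_id
  n_clusters <- length(unique(cl))
  if (n_clusters < 2)
    jx_stop("at least 2 clusters are required for the empirical covariance",
            "jx_variance_error")
  ybar <- stats::weighted.mean(y, w)
  if (ybar <= 0 || ybar >= 1)
    jx_stop("degenerate response: all observations in one outcome class",
            "jx_separation_error")

  beta <- rep(0, ncol(X)); names(beta) <- colnames(X)
  rho <- NULL
  ## estimating function and its derivative at beta, for the active structure
  ef <- function(beta, with_H = TRUE) {
    eta <- drop(X %*% beta)
    mu <- .expit(eta)
    v <- mu * (1 - mu)
    if (wc$kind == "independence") {
      list(U = crossprod(X, w * (y - mu)),
           H = if (with_H) crossprod(X, X * (w * v)))
    } else {
      su <- .gee_cluster_sums(y, mu, v, w, X, cl, design$pair_classes, rho)
      list(U = su$U, H = if (with_H) su$H)
    }
  }
  converged <- FALSE; it <- 0L
  for (it in seq_len(max_iter)) {
    if (wc$kind == "relationship") {
      eta <- drop(X %*% beta)
      mu <- .expit(eta); v <- mu * (1 - mu)
      rho <- .estimate_class_corr(y, mu, v, w, cl, design$pair_classes,
                                  wc$classes, p = ncol(X))
    }
    cur <- ef(beta)
    step <- solve(cur$H, cur$U)
    f0 <- sum(cur$U^2)
    lambda <- 1
    repeat {
      beta_new <- beta + lambda * drop(step)
      f1 <- sum(ef(beta_new, with_H = FALSE)$U^2)
      if ((is.finite(f1) && f1 <= f0 * (1 + 1e-8)) || lambda < 1 / 1024) break
      lambda <- lambda / 2
    }
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    names(beta) <- colnames(X)
    if (delta < tol) { converged <- TRUE; break }
  }
  eta <- drop(X %*% beta)
  mu <- .expit(eta)
  v <- mu * (1 - mu)
  separation <- any(abs(eta) > 30)
  if (separation)
    warning("possible separation: |linear predictor| > 30 at convergence")

  if (wc$kind == "independence") {
    bread_inv <- crossprod(X, X * (w * v))
    sc <- X * (w * (y - mu))
    meat <- .cluster_meat(sc, cl)
  } else {
    su <- .gee_cluster_sums(y, mu, v, w, X, cl, design$pair_classes, rho,
                            meat = TRUE)
    bread_inv <- su$H
    meat <- su$M
  }
  bread <- solve(bread_inv)
  robust <- bread %*% meat %*% bread
  robust <- (robust + t(robust)) / 2
  naive <- (bread + t(bread)) / 2
  dimnames(robust) <- dimnames(naive) <- list(colnames(X), colnames(X))
  structure(list(coefficients = beta, robust_vcov = robust,
                 naive_vcov = naive, fitted = mu, linear_predictor = eta,
                 response = y, design_matrix = X, cluster_id = cl,
                 n_obs = nrow(X), n_clusters = n_clusters,
                 iterations = it, converged = converged,
                 separation = separation, working_correlations = rho,
                 kind = "logistic"),
            class = "jx_fit")
}

## sum of per-cluster score outer products
.cluster_meat <- function(scores, cl) {
  S <- rowsum(scores, cl)
  crossprod(S)
}

## moment estimates of one correlation per relative-pair class
.estimate_class_corr <- function(y, mu, v, w, cl, pair_classes, classes, p) {
  if (is.null(pair_classes) || !nrow(pair_classes))
    return(stats::setNames(rep(0, length(classes)), classes))
  r <- (y - mu) / sqrt(pmax(v, 1e-10))
  i1 <- pair_classes$id1; i2 <- pair_classes$id2
  prod_r <- r[i1] * r[i2]
  out <- stats::setNames(rep(0, length(classes)), classes)
  for (cls in classes) {
    sel <- pair_classes$class == cls
    ncl <- sum(sel)
    if (ncl > p) out[cls] <- sum(prod_r[sel]) / (ncl - p)
  }
  pmin(pmax(out, -0.95), 0.95)
}

## cluster-level D' V^{-1} D, D' V^{-1} (y - mu) and optional meat under a
## relationship-specific working correlation; working matrices that are not
## positive definite are shrunk toward the identity
.gee_cluster_sums <- function(y, mu, v, w, X, cl, pair_classes, rho,
                              meat = FALSE) {
  p <- ncol(X)
  H <- matrix(0, p, p); U <- matrix(0, p, 1); M <- matrix(0, p, p)
  pc_by_cl <- NULL
  if (!is.null(pair_classes) && nrow(pair_classes))
    pc_by_cl <- split(pair_classes, cl[pair_classes$id1])
  row_of <- split(seq_along(cl), cl)
  for (fam in names(row_of)) {
    idx <- row_of[[fam]]
    ni <- length(idx)
    sdv <- sqrt(pmax(v[idx], 1e-10))
    R <- diag(ni)
    pc <- pc_by_cl[[fam]]
    if (!is.null(pc) && nrow(pc)) {
      pos <- match(pc$id1, idx); pos2 <- match(pc$id2, idx)
      rr <- rho[pc$class]; rr[is.na(rr)] <- 0
      for (k in seq_len(nrow(pc))) {
        R[pos[k], pos2[k]] <- R[pos2[k], pos[k]] <- rr[k]
      }
      ev_min <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
      if (ev_min <= 1e-6) {
        ## scale off-diagonals by the largest factor restoring PD
        s <- (1 - 1e-6) / (1 - ev_min + 1e-12)
        R <- s * R + (1 - s) * diag(ni)
      }
    }
    ## prior weights enter through the variance: V_i = A^{1/2} R A^{1/2} / w
    sdv_w <- sdv / sqrt(w[idx])
    Vi <- R * outer(sdv_w, sdv_w)
    Vinv <- solve(Vi)
    Di <- X[idx, , drop = FALSE] * v[idx]
    DtV <- crossprod(Di, Vinv)
    H <- H + DtV %*% Di
    ui <- DtV %*% (y[idx] - mu[idx])
    U <- U + ui
    if (meat) M <- M + tcrossprod(ui)
  }
  list(H = H, U = U, M = M)
}

#' Fit a baseline-category polytomous model to clustered data
#'
#' Baseline-category (multinomial) logit estimating equations under working
#' independence with an empirical cluster-level sandwich covariance: the
#' point estimates solve the multinomial logistic score equations as if
#' observations were independent, and the covariance is robust to
#' within-family dependence.  Coefficients come in one block per non-reference
#' category, named `"<category>:<term>"`.
#'
#' @param design A [clustered_design()] whose response is a factor/character
#'   of category labels (first level = reference) or an n-by-K matrix of
#'   nonnegative category weights with column names (first column =
#'   reference).
#' @param ref Reference category label; defaults to the first factor level /
#'   first column.
#' @param tol,max_iter As in [fit_logistic_gee()].
#' @return A `"jx_fit"` with `kind = "polytomous"`, plus `categories` (the
#'   non-reference category labels in block order) and `terms` (the design
#'   column names of one block).
#' @export
fit_polytomous_gee <- function(design, ref = NULL, tol = 1e-8,
                               max_iter = 100L) {
  X <- design$design_matrix
  y <- design$response
  w <- design$weights
  cl <- design$cluster_id
  if (is.matrix(y)) {
    Ymat <- y * w
    cats <- colnames(Ymat)
    if (is.null(cats)) cats <- paste0("cat", seq_len(ncol(Ymat)))
    if (!is.null(ref)) {
      stopifnot(ref %in% cats)
      Ymat <- Ymat[, c(ref, setdiff(cats, ref)), drop = FALSE]
      cats <- colnames(Ymat)
    }
  } else {
    yf <- if (is.factor(y)) y else factor(y)
    if (!is.null(ref)) yf <- stats::relevel(yf, ref = as.character(ref))
    cats <- levels(yf)
    Ymat <- matrix(0, nrow(X), length(cats), dimnames = list(NULL, cats))
    Ymat[cbind(seq_len(nrow(X)), as.integer(yf))] <- w
  }
  K <- ncol(Ymat)
  if (K < 2) jx_stop("need at least 2 categories", "jx_category_error")
  empty <- colSums(Ymat) <= 0
  if (any(empty))
    jx_stop(sprintf("category(ies) with no observations: %s",
                    paste(cats[empty], collapse = ", ")),
            "jx_category_error")
  n_clusters <- length(unique(cl))
  if (n_clusters < 2)
    jx_stop("at least 2 clusters are required for the empirical covariance",
            "jx_variance_error")
  p <- ncol(X)
  nb <- K - 1L                       # non-reference blocks
  beta <- matrix(0, p, nb)           # one column per block
  rs <- rowSums(Ymat)                # per-row total weight

  loglik <- function(beta) {
    Eta <- X %*% beta
    A <- cbind(0, Eta)
    m <- apply(A, 1, max)
    lse <- m + log(rowSums(exp(A - m)))
    sum(Ymat * A) - sum(rs * lse)
  }
  probs <- function(beta) {
    Eta <- X %*% beta
    A <- cbind(0, Eta)
    A <- exp(A - apply(A, 1, max))
    A / rowSums(A)
  }
  ll <- loglik(beta)
  converged <- FALSE; it <- 0L
  for (it in seq_len(max_iter)) {
    P <- probs(beta)
    ## score per block: X'(y_k - n_i p_k)
    Resid <- Ymat[, -1, drop = FALSE] - rs * P[, -1, drop = FALSE]
    U <- as.vector(crossprod(X, Resid))            # p*nb vector, block-major
    ## Fisher information: blocks (j,k) = X' diag(n p_j (1[j=k] - p_k)) X
    Hmat <- matrix(0, p * nb, p * nb)
    for (jb in seq_len(nb)) for (kb in jb:nb) {
      wjk <- rs * P[, jb + 1] * ((jb == kb) - P[, kb + 1])
      blk <- crossprod(X, X * wjk)
      ri <- (jb - 1) * p + seq_len(p); ci <- (kb - 1) * p + seq_len(p)
      Hmat[ri, ci] <- blk
      if (jb != kb) Hmat[ci, ri] <- t(blk)
    }
    step <- solve(Hmat, U)
    lambda <- 1
    repeat {
      beta_new <- beta + lambda * matrix(step, p, nb)
      ll_new <- loglik(beta_new)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1 / 4096) break
    }
    delta <- max(abs(beta_new - beta))
    beta <- beta_new; ll <- loglik(beta)
    if (delta < tol) { converged <- TRUE; break }
  }
  P <- probs(beta)
  Eta <- X %*% beta
  separation <- any(abs(Eta) > 30)
  if (separation)
    warning("possible separation: |linear predictor| > 30 at convergence")
  ## sandwich
  Resid <- Ymat[, -1, drop = FALSE] - rs * P[, -1, drop = FALSE]
  scores <- do.call(cbind, lapply(seq_len(nb), function(k) X * Resid[, k]))
  meat <- .cluster_meat(scores, cl)
  Hmat <- matrix(0, p * nb, p * nb)
  for (jb in seq_len(nb)) for (kb in jb:nb) {
    wjk <- rs * P[, jb + 1] * ((jb == kb) - P[, kb + 1])
    blk <- crossprod(X, X * wjk)
    ri <- (jb - 1) * p + seq_len(p); ci <- (kb - 1) * p + seq_len(p)
    Hmat[ri, ci] <- blk
    if (jb != kb) Hmat[ci, ri] <- t(blk)
  }
  bread <- solve(Hmat)
  robust <- bread %*% meat %*% bread
  robust <- (robust + t(robust)) / 2
  naive <- (bread + t(bread)) / 2
  coef_names <- as.vector(vapply(cats[-1], function(cc)
    paste0(cc, ":", colnames(X)), character(p)))
  cf <- stats::setNames(as.vector(beta), coef_names)
  dimnames(robust) <- dimnames(naive) <- list(coef_names, coef_names)
  structure(list(coefficients = cf, robust_vcov = robust,
                 naive_vcov = naive, fitted = P,
                 linear_predictor = Eta, response = Ymat,
                 design_matrix = X, cluster_id = cl,
                 n_obs = nrow(X), n_clusters = n_clusters,
                 iterations = it, converged = converged,
                 separation = separation, working_correlations = NULL,
                 categories = cats[-1], reference = cats[1],
                 terms = colnames(X), kind = "polytomous"),
            class = "jx_fit")
}

#' Extract the empirical (sandwich) covariance from a fit
#' @param fit A `"jx_fit"`.
#' @return The robust covariance matrix of the coefficient estimates.
#' @export
robust_vcov <- function(fit) fit$robust_vcov

#' @export
print.jx_fit <- function(x, ...) {
  cat(sprintf("%s GEE fit: %d obs in %d clusters, %d iterations%s\n",
              x$kind, x$n_obs, x$n_clusters, x$iterations,
              if (x$converged) "" else " (NOT converged)"))
  tab <- data.frame(estimate = x$coefficients,
                    robust_se = sqrt(diag(x$robust_vcov)),
                    naive_se = sqrt(diag(x$naive_vcov)))
  print(round(tab, 4))
  if (!is.null(x$working_correlations)) {
    cat("working correlations:\n")
    print(round(x$working_correlations, 3))
  }
  invisible(x)
}

#' Coefficient summary table of a fit
#'
#' @param fit A `"jx_fit"`.
#' @return Data frame with columns `term`, `estimate`, `robust_se`,
#'   `naive_se`.
#' @export
fit_summary <- function(fit) {
  data.frame(term = names(fit$coefficients),
             estimate = unname(fit$coefficients),
             robust_se = sqrt(diag(fit$robust_vcov)),
             naive_se = sqrt(diag(fit$naive_vcov)),
             row.names = NULL, stringsAsFactors = FALSE)
}
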