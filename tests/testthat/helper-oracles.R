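## Independent oracles used to check the estimating-equation solvers.
## These are deliberately written as plain brute-force implementations,
## sharing no code with the package internals.

## logistic ML by plain Newton-Raphson on the log-likelihood
oracle_logistic_ml <- function(X, y, tol = 1e-12, iter = 50) {
  b <- rep(0, ncol(X))
  for (i in seq_len(iter)) {
    p <- 1 / (1 + exp(-drop(X %*% b)))
    grad <- t(X) %*% (y - p)
    info <- t(X) %*% (X * (p * (1 - p)))
    step <- solve(info, grad)
    b <- b + step
    if (max(abs(step)) < tol) break
  }
  drop(b)
}

## multinomial logistic ML by BFGS on the (analytic-gradient) log-likelihood;
## Ymat columns: reference first.  Returns block-major coefficients
## (category 2 block, category 3 block, ...).
oracle_multinomial_ml <- function(X, Ymat) {
  p <- ncol(X); K <- ncol(Ymat); nb <- K - 1
  negll <- function(th) {
    B <- matrix(th, p, nb)
    A <- cbind(0, X %*% B)
    m <- apply(A, 1, max)
    lse <- m + log(rowSums(exp(A - m)))
    -(sum(Ymat * A) - sum(rowSums(Ymat) * lse))
  }
  grad <- function(th) {
    B <- matrix(th, p, nb)
    A <- exp(cbind(0, X %*% B))
    P <- A / rowSums(A)
    R <- Ymat[, -1, drop = FALSE] - rowSums(Ymat) * P[, -1, drop = FALSE]
    -as.vector(t(X) %*% R)
  }
  o <- stats::optim(rep(0, p * nb), negll, grad, method = "BFGS",
                    control = list(maxit = 2000, reltol = 1e-15))
  o$par
}

## textbook cluster sandwich for a logistic fit, assembled with dense loops
oracle_logistic_sandwich <- function(X, y, beta, cluster) {
  p <- 1 / (1 + exp(-drop(X %*% beta)))
  B <- matrix(0, ncol(X), ncol(X))
  M <- matrix(0, ncol(X), ncol(X))
  for (g in unique(cluster)) {
    idx <- which(cluster == g)
    Xi <- X[idx, , drop = FALSE]
    Wi <- diag(p[idx] * (1 - p[idx]), nrow = length(idx))
    B <- B + t(Xi) %*% Wi %*% Xi
    si <- t(Xi) %*% (y[idx] - p[idx])
    M <- M + si %*% t(si)
  }
  solve(B) %*% M %*% solve(B)
}

## relationship classification by explicit ancestor-path enumeration:
## all ancestor chains of each subject are listed, then the pair class is
## read off the chain structure (a deliberately different algorithm from
## the package's parent-set rules)
oracle_classify <- function(ped, i, j) {
  id <- ped$id
  par_of <- function(s) {
    k <- match(s, id)
    c(ped$father_id[k], ped$mother_id[k])
  }
  ## list of ancestor paths (each a vector starting at the subject)
  paths <- function(s) {
    pp <- par_of(s)
    if (all(is.na(pp))) return(list(s))
    out <- list(s)
    for (q in pp[!is.na(pp)])
      out <- c(out, lapply(paths(q), function(pa) c(s, pa)))
    out
  }
  pi <- paths(i); pj <- paths(j)
  ## depth of each ancestor (shortest chain)
  depth_map <- function(pl) {
    m <- list()
    for (pa in pl) for (d in seq_along(pa)) {
      a <- pa[d]
      if (is.null(m[[a]]) || m[[a]] > d - 1) m[[a]] <- d - 1
    }
    m
  }
  di <- depth_map(pi); dj <- depth_map(pj)
  common <- intersect(names(di), names(dj))
  if (!is.na(match(j, names(di))) && di[[j]] == 1) return("parent-offspring")
  if (!is.na(match(i, names(dj))) && dj[[i]] == 1) return("parent-offspring")
  shared2 <- common[vapply(common, function(a) di[[a]] == 1 && dj[[a]] == 1,
                           logical(1))]
  if (length(shared2) == 2) return("sibling")
  if ((j %in% names(di) && di[[j]] == 2) ||
      (i %in% names(dj) && dj[[i]] == 2)) return("grandparent-grandchild")
  ## avuncular: i full sib of a parent of j (or vice versa)
  full_sibs <- function(a, b) {
    pa <- par_of(a); pb <- par_of(b)
    !anyNA(pa) && !anyNA(pb) && setequal(pa, pb)
  }
  for (q in par_of(j)) if (!is.na(q) && full_sibs(i, q)) return("avuncular")
  for (q in par_of(i)) if (!is.na(q) && full_sibs(j, q)) return("avuncular")
  for (qi in par_of(i)) for (qj in par_of(j))
    if (!is.na(qi) && !is.na(qj) && qi != qj && full_sibs(qi, qj))
      return("first-cousin")
  ## spouse: common offspring
  for (s in id) {
    pp <- par_of(s)
    if (!anyNA(pp) && setequal(pp, c(i, j))) return("spouse")
  }
  "other"
}
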