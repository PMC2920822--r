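## Independent oracles used by the tests.  These deliberately re-derive each
## quantity by a different route than the package (different algorithm,
## different parameterization) so that agreement is informative.

## Fused-lasso constrained least squares solved by sequential quadratic
## programming (nloptr::slsqp) on a smooth formulation that differs from the
## package's: beta is split as u - v (u, v >= 0) and each fusion difference
## is split as e - f via equality constraints, rather than bounded by
## auxiliary variables.
oracle_fused_lasso <- function(X, y, pairs, w, s1, s2, V = NULL) {
  n <- nrow(X); p <- ncol(X)
  m <- if (is.null(pairs)) 0L else nrow(pairs)
  iu <- 1:p; iv <- (p + 1):(2 * p); ib <- 2 * p + 1
  ie <- if (m > 0) (2 * p + 2):(2 * p + 1 + m) else integer(0)
  iff <- if (m > 0) (2 * p + 1 + m + 1):(2 * p + 1 + 2 * m) else integer(0)
  N <- 2 * p + 1 + 2 * m
  fn <- function(z) {
    beta <- z[iu] - z[iv]
    sum((y - X %*% beta - z[ib])^2)
  }
  gr <- function(z) {
    beta <- z[iu] - z[iv]
    r <- as.vector(y - X %*% beta - z[ib])
    g <- numeric(N)
    gb <- -2 * as.vector(crossprod(X, r))
    g[iu] <- gb; g[iv] <- -gb; g[ib] <- -2 * sum(r)
    g
  }
  hin <- function(z) c(sum(z[iu] + z[iv]) - s1,          # <= 0
                       if (m > 0) sum(z[ie] + z[iff]) - s2)
  heq <- function(z) {
    beta <- z[iu] - z[iv]
    out <- if (m > 0) {
      w * (beta[pairs[, 2]] - beta[pairs[, 1]]) - (z[ie] - z[iff])
    } else numeric(0)
    if (!is.null(V) && nrow(V) > 0) out <- c(out, as.vector(V %*% beta))
    out
  }
  z0 <- numeric(N); z0[ib] <- mean(y)
  res <- nloptr::slsqp(z0, fn, gr = gr, hin = hin, heq = heq,
                       lower = c(rep(0, 2 * p), -Inf, rep(0, 2 * m)),
                       control = list(xtol_rel = 1e-14, maxeval = 20000),
                       deprecatedBehavior = FALSE)
  beta <- res$par[iu] - res$par[iv]
  bias <- res$par[ib]
  list(beta = beta, bias = bias,
       objective = sum((y - X %*% beta - bias)^2))
}

## One-sided (enrichment) Fisher p-value by exhaustive hypergeometric
## enumeration with exact binomial coefficients.
oracle_fisher_greater <- function(n11, n10, n01, n00) {
  r1 <- n11 + n10; c1 <- n11 + n01; n <- n11 + n10 + n01 + n00
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  ks <- ks[ks >= n11]
  sum(choose(c1, ks) * choose(n - c1, r1 - ks)) / choose(n, r1)
}

## Unconstrained least-squares fit via the pseudoinverse (limit oracle).
oracle_lsq <- function(X, y) {
  C <- cbind(X, 1)
  coef <- as.vector(MASS::ginv(C) %*% y)
  p <- ncol(X)
  list(beta = coef[1:p], bias = coef[p + 1],
       objective = sum((y - C %*% coef)^2))
}

## Adjusted Rand index between two labelings (mclust's implementation is the
## independent reference used throughout).
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

## Random small fused-lasso instance for oracle-equivalence sweeps.
random_qp_instance <- function(seed) {
  set.seed(seed)
  n <- sample(3:6, 1); p <- sample(3:8, 1)
  X <- matrix(rnorm(n * p), n, p)
  y <- sample(c(-1, 1), n, replace = TRUE)
  pairs <- cbind(1:(p - 1), 2:(p - 1 + 1))
  w <- runif(p - 1, 0.3, 1)
  list(X = X, y = y, pairs = pairs, w = w,
       s1 = runif(1, 0.1, 5), s2 = runif(1, 0.1, 5),
       V = if (seed %% 3 == 0) matrix(rnorm(p), 1, p) else NULL)
}

## Wrap raw pieces as the package's fusion_weights structure.
as_fusion_weights <- function(pairs, weights) {
  structure(list(pairs = pairs, weights = weights, form = "uniform",
                 scale_used = NA_real_),
            class = "fusion_weights")
}

## Chain probe map on one chromosome with unit gaps (simple test fixture).
chain_probe_map <- function(p, chromosome = "1", gap = 1000) {
  make_probe_map(p, "uniform", chromosome = chromosome, gap = gap)
}

## Feasibility check of a separator against its budgets.
constraint_violation <- function(sep, weights, params, orthogonal_to = list()) {
  v <- max(0, sum(abs(sep$beta)) - params$s1)
  if (!is.null(weights) && nrow(weights$pairs)) {
    fuse <- sum(weights$weights *
                abs(sep$beta[weights$pairs[, 2]] - sep$beta[weights$pairs[, 1]]))
    v <- max(v, fuse - params$s2)
  }
  for (u in orthogonal_to) v <- max(v, abs(sum(sep$beta * u)))
  v
}
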