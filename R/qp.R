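#' Fused-lasso constraint budgets and loop controls
#'
#' `s1` is the sparseness budget (upper bound on `sum(abs(beta))`), `s2` the
#' piecewise-constantness budget (upper bound on the distance-weighted total
#' variation `sum(w * abs(diff(beta)))` over fused pairs).  Both are
#' platform-dependent; see the methods vignette for the grid-search recipe.
#'
#' @param s1 nonnegative sparsity budget (default 2).
#' @param s2 nonnegative fusion budget (default 1).
#' @param max_iter maximum alternating iterations in [mmc_partition()]
#'   (default 50).
#' @param seed integer seed controlling k-means initialization.
#' @return A list of class `fused_lasso_params`.
#' @export
fused_lasso_params <- function(s1 = 2, s2 = 1, max_iter = 50L, seed = 1L) {
  stopifnot(is_scalar_num(s1), s1 >= 0, is_scalar_num(s2), s2 >= 0,
            is_count(max_iter), is_count(seed, min = 0L))
  structure(list(s1 = as.double(s1), s2 = as.double(s2),
                 max_iter = as.integer(max_iter), seed = as.integer(seed)),
            class = "fused_lasso_params")
}

new_separator <- function(beta, bias, labels = NULL, objective = NA_real_) {
  structure(list(beta = as.double(beta), bias = as.double(bias),
                 labels = labels, objective = objective),
            class = "separator")
}

#' @export
print.separator <- function(x, ...) {
  cat(sprintf("separator: %d probes, %d non-zero weights, bias %.4g\n",
              length(x$beta), sum(abs(x$beta) > 1e-8), x$bias))
  invisible(x)
}

#' Assign group labels from a linear separator
#'
#' Labels are `sign(beta . x + bias)` with ties (decision value exactly 0)
#' assigned +1.
#'
#' @param separator a `separator` (from [solve_qp()] or [mmc_partition()]).
#' @param X numeric matrix or [profile_matrix()].
#' @return Integer vector of labels in \{-1, +1\}.
#' @export
assign_labels <- function(separator, X) {
  if (inherits(X, "profile_matrix")) X <- X$values
  dec <- as.vector(X %*% separator$beta + separator$bias)
  unname(ifelse(dec >= 0, 1L, -1L))
}

## Build the QP in compact quadprog form.
## Variables z = (beta[1..p], bias, a[1..p], t[1..m]):
##   a_j >= |beta_j| via a_j - beta_j >= 0, a_j + beta_j >= 0; sum(a) <= s1
##   t_k >= w_k |beta_to - beta_from| likewise; sum(t) <= s2
## Objective ||y - X beta - bias||^2; orthogonality rows are equalities.
fl_qp_build <- function(X, y, pairs, w, s1, s2, V, ridge) {
  n <- nrow(X); p <- ncol(X)
  m <- if (is.null(pairs)) 0L else nrow(pairs)
  N <- 2L * p + 1L + m
  ib <- seq_len(p); ibias <- p + 1L; ia <- (p + 2L):(2L * p + 1L)
  it <- if (m > 0L) (2L * p + 2L):(2L * p + 1L + m) else integer(0)
  C <- cbind(X, 1)
  D <- matrix(0, N, N)
  D[seq_len(p + 1L), seq_len(p + 1L)] <- 2 * crossprod(C)
  diag(D) <- diag(D) + ridge * max(diag(D))
  dvec <- numeric(N)
  dvec[seq_len(p + 1L)] <- 2 * crossprod(C, y)

  nV <- if (is.null(V)) 0L else nrow(V)
  q <- nV + 2L * p + 1L + (if (m > 0L) 2L * m + 1L else 0L)
  kmax <- max(2L, p, m, if (nV) p else 0L)
  Amat <- matrix(0, kmax, q)
  Aind <- matrix(0L, kmax + 1L, q)
  bvec <- numeric(q)
  col <- 0L
  put <- function(idx, val, rhs) {
    col <<- col + 1L
    k <- length(idx)
    Aind[1L, col] <<- k
    Aind[seq_len(k) + 1L, col] <<- idx
    Amat[seq_len(k), col] <<- val
    bvec[col] <<- rhs
  }
  if (nV) for (k in seq_len(nV)) put(ib, V[k, ], 0)
  for (j in seq_len(p)) put(c(ia[j], ib[j]), c(1, -1), 0)
  for (j in seq_len(p)) put(c(ia[j], ib[j]), c(1, 1), 0)
  put(ia, rep(-1, p), -s1)
  if (m > 0L) {
    for (k in seq_len(m)) {
      put(c(it[k], ib[pairs[k, 2L]], ib[pairs[k, 1L]]), c(1, -w[k], w[k]), 0)
    }
    for (k in seq_len(m)) {
      put(c(it[k], ib[pairs[k, 2L]], ib[pairs[k, 1L]]), c(1, w[k], -w[k]), 0)
    }
    put(it, rep(-1, m), -s2)
  }
  list(D = D, dvec = dvec, Amat = Amat, Aind = Aind, bvec = bvec,
       meq = nV, ib = ib, ibias = ibias)
}

#' Solve the fused-lasso constrained least-squares problem
#'
#' Minimizes `sum((y - X beta - bias)^2)` subject to the sparsity budget
#' `sum(abs(beta)) <= s1`, the fusion budget
#' `sum(w * abs(beta[to] - beta[from])) <= s2` over adjacent same-arm probe
#' pairs, and `beta . v = 0` for every vector `v` in `orthogonal_to`.
#' Absolute values are linearized exactly by auxiliary bound variables, so the
#' problem is a convex quadratic program, solved with a dual active-set
#' method (`quadprog::solve.QP.compact`).  A relative ridge of `ridge *
#' max(diag(H))` makes the rank-deficient least-squares Hessian strictly
#' positive definite, as the solver requires.
#'
#' `s1 = 0` is handled analytically: `beta = 0` exactly and
#' `bias = mean(y)`.
#'
#' @param X numeric matrix (samples x probes) or [profile_matrix()].
#' @param y numeric response vector; in the clustering loop these are the
#'   current +/-1 labels used as regression targets.
#' @param weights a [compute_fusion_weights()] result, or `NULL` for no
#'   fusion constraint.
#' @param params a [fused_lasso_params()].
#' @param orthogonal_to list of length-p vectors the solution must be
#'   orthogonal to (weight vectors of previously learned separators).
#' @param ridge relative ridge regularization (default 1e-10).
#' @param check_tol feasibility tolerance for the post-solve constraint check
#'   (default 1e-6).
#' @return A `separator` with fields `beta`, `bias`, `objective` (residual
#'   sum of squares); `labels` is unset.
#' @export
solve_qp <- function(X, y, weights, params, orthogonal_to = list(),
                     ridge = 1e-10, check_tol = 1e-6) {
  if (inherits(X, "profile_matrix")) X <- X$values
  X <- as.matrix(X)
  y <- as.double(y)
  stopifnot(nrow(X) == length(y), inherits(params, "fused_lasso_params"))
  if (anyNA(X)) stop("X contains missing values", call. = FALSE)
  p <- ncol(X)
  pairs <- NULL; w <- NULL
  if (!is.null(weights)) {
    stopifnot(inherits(weights, "fusion_weights"))
    pairs <- weights$pairs; w <- weights$weights
    if (nrow(pairs) && max(pairs) > p) {
      stop("fusion pairs index beyond ncol(X)", call. = FALSE)
    }
  }
  V <- NULL
  if (length(orthogonal_to)) {
    V <- do.call(rbind, lapply(orthogonal_to, as.double))
    if (ncol(V) != p) stop("orthogonal_to vectors must have length p", call. = FALSE)
    if (qr(t(V))$rank >= p) {
      stop("orthogonality constraints span the full probe space (rank >= p)",
           call. = FALSE)
    }
  }

  if (params$s1 == 0) {
    beta <- numeric(p); bias <- mean(y)
    return(new_separator(beta, bias,
                         objective = sum((y - bias)^2)))
  }

  qp <- fl_qp_build(X, y, pairs, w, params$s1, params$s2, V, ridge)
  sol <- tryCatch(
    quadprog::solve.QP.compact(qp$D, qp$dvec, qp$Amat, qp$Aind, qp$bvec,
                               meq = qp$meq),
    error = function(e) {
      stop("fused-lasso QP failed (n = ", nrow(X), ", p = ", p, ", s1 = ",
           params$s1, ", s2 = ", params$s2, "): ", conditionMessage(e),
           call. = FALSE)
    })
  beta <- sol$solution[qp$ib]
  bias <- sol$solution[qp$ibias]

  viol <- max(0, sum(abs(beta)) - params$s1)
  if (!is.null(pairs) && nrow(pairs)) {
    fuse <- sum(w * abs(beta[pairs[, 2L]] - beta[pairs[, 1L]]))
    viol <- max(viol, fuse - params$s2)
  }
  if (!is.null(V)) viol <- max(viol, max(abs(V %*% beta)))
  if (viol > check_tol) {
    stop(sprintf("QP solution violates constraints by %.3g (tolerance %.1g)",
                 viol, check_tol), call. = FALSE)
  }
  new_separator(beta, bias,
                objective = sum((y - X %*% beta - bias)^2))
}
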