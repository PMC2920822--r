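#' Group centroid (median profile)
#'
#' Each sample group is represented by its centroid: the per-probe median of
#' the member profiles.
#'
#' @param X [profile_matrix()] or numeric matrix.
#' @param members logical vector over samples, or integer indices; must
#'   select at least one sample.
#' @return Numeric vector over probes.
#' @export
centroid <- function(X, members) {
  if (inherits(X, "profile_matrix")) X <- X$values
  sub <- X[members, , drop = FALSE]
  if (nrow(sub) == 0L) stop("centroid of an empty group is undefined", call. = FALSE)
  matrixStats::colMedians(sub)
}

## Euclidean distance between the two group centroids of a labeling;
## 0 when either group is empty.
centroid_distance <- function(X, labels) {
  if (all(labels > 0) || all(labels < 0)) return(0)
  sqrt(sum((matrixStats::colMedians(X[labels > 0, , drop = FALSE]) -
            matrixStats::colMedians(X[labels < 0, , drop = FALSE]))^2))
}

#' Probe-permutation significance of a split
#'
#' Tests whether the two groups induced by a separator are farther apart
#' than groups produced by the same frozen classifier on probe-shuffled
#' data.  The observed statistic is the Euclidean distance between the two
#' group centroids (median profiles).  For each of `n_perm` iterations the
#' probe values are shuffled, the frozen separator
#' (`sign(beta . x + bias)`) is re-applied to the shuffled profiles to
#' define two random sample groups, and their centroid distance on the
#' shuffled data is recorded (0 when a group is empty).  A normal
#' distribution is fitted to the null distances and
#' `p = 1 - pnorm((observed - mean) / sd)`.
#'
#' Two shuffling schemes are provided.  The default, `"within-probe"`,
#' independently permutes each probe's values across samples: every probe
#' keeps its cohort-level value distribution, but the within-sample
#' correlation structure that ties a CNA to a coherent set of samples is
#' destroyed, so the classifier's group assignment becomes unrelated to the
#' true carrier structure.  This scheme has power against events of every
#' span, from focal to whole-chromosome.  The alternative,
#' `"joint-columns"`, applies one shared permutation of the probe columns to
#' all samples; it preserves inter-sample geometry exactly (a coordinate
#' permutation) and is therefore blind to events spanning most of the
#' chromosome — a whole-chromosome gain is literally invariant under it —
#' so it is kept only for comparison on focal events.
#'
#' @param X [profile_matrix()] or numeric matrix.
#' @param separator a `separator` whose `labels` define the observed groups
#'   (recomputed from the decision function if unset).
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed for the permutation stream.
#' @param scheme `"within-probe"` (default) or `"joint-columns"`, see
#'   Details.
#' @return An object of class `significance_result`: `observed_distance`,
#'   `null_mean`, `null_sd`, `p_value`, `n_perm`, `degenerate` flag.
#' @export
split_significance <- function(X, separator, n_perm = 1000L, seed = 1L,
                               scheme = c("within-probe", "joint-columns")) {
  if (inherits(X, "profile_matrix")) X <- X$values
  scheme <- match.arg(scheme)
  stopifnot(is_count(n_perm))
  labels <- separator$labels %||% assign_labels(separator, X)
  stopifnot(length(labels) == nrow(X))

  if (all(labels > 0) || all(labels < 0)) {
    return(structure(list(observed_distance = 0, null_mean = NA_real_,
                          null_sd = NA_real_, p_value = 1,
                          n_perm = 0L, degenerate = TRUE),
                     class = "significance_result"))
  }
  observed <- centroid_distance(X, labels)

  n <- nrow(X); p <- ncol(X)
  beta <- separator$beta
  set.seed(seed)
  null_dist <- vapply(seq_len(n_perm), function(b) {
    if (scheme == "within-probe") {
      Xs <- apply(X, 2L, sample)
      lab <- unname(ifelse(as.vector(Xs %*% beta) + separator$bias >= 0,
                           1L, -1L))
      centroid_distance(Xs, lab)
    } else {
      perm <- sample.int(p)
      ## labels of X[, perm]: X[, perm] %*% beta == X %*% beta[inv(perm)]
      bp <- numeric(p); bp[perm] <- beta
      lab <- unname(ifelse(as.vector(X %*% bp) + separator$bias >= 0,
                           1L, -1L))
      ## the Euclidean centroid distance is invariant under a shared column
      ## permutation, so it can be computed on the unpermuted matrix
      centroid_distance(X, lab)
    }
  }, 0)

  mu <- mean(null_dist)
  sdv <- sd(null_dist)
  if (!is.finite(sdv) || sdv == 0) {
    pval <- if (observed > mu) 0 else 1
    degenerate <- TRUE
  } else {
    pval <- 1 - pnorm((observed - mu) / sdv)
    degenerate <- FALSE
  }
  structure(list(observed_distance = observed, null_mean = mu,
                 null_sd = if (is.finite(sdv)) sdv else NA_real_,
                 p_value = pval, n_perm = as.integer(n_perm),
                 degenerate = degenerate),
            class = "significance_result")
}

#' @export
print.significance_result <- function(x, ...) {
  cat(sprintf(
    "split significance: observed %.4g, null %.4g +/- %.4g, p = %.4g (%d perms)%s\n",
    x$observed_distance, x$null_mean, x$null_sd, x$p_value, x$n_perm,
    if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}
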