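#' Distance-normalized fusion weights between adjacent probes
#'
#' Builds one fusion relation per pair of successive probes lying on the same
#' chromosomal arm; pairs never span an arm or chromosome boundary.  The
#' weight down-weights the piecewise-constantness coupling across large
#' genomic gaps, where adjacent probes are less likely to share copy number.
#'
#' The default form is `w = min(1, scale / d)` with `d` the base-pair gap and
#' `scale` the median gap over all emitted pairs (`scale = "auto"`): probes at
#' or below the typical spacing are fully coupled (weight 1) and the coupling
#' decays inversely beyond it.  `form = "uniform"` sets every weight to 1,
#' recovering the unweighted fused lasso.
#'
#' @param probe_map a [probe_map()].
#' @param form `"inverse-distance"` (default) or `"uniform"`.
#' @param scale positive number, or `"auto"` for the median emitted gap.
#' @return An object of class `fusion_weights`: list with `pairs` (2-column
#'   integer matrix of probe indices into `probe_map`), `weights` in (0, 1],
#'   `form`, and `scale_used`.
#' @export
compute_fusion_weights <- function(probe_map,
                                   form = c("inverse-distance", "uniform"),
                                   scale = "auto") {
  form <- match.arg(form)
  validate_probe_map(probe_map)
  p <- nrow(probe_map)
  same_block <- probe_map$chromosome[-1L] == probe_map$chromosome[-p] &
    probe_map$arm[-1L] == probe_map$arm[-p]
  lo <- which(same_block)
  pairs <- cbind(lo, lo + 1L)
  colnames(pairs) <- c("from", "to")
  gaps <- probe_map$position[pairs[, 2L]] - probe_map$position[pairs[, 1L]]
  if (any(gaps <= 0)) stop("nonpositive inter-probe gap", call. = FALSE)
  if (form == "uniform") {
    weights <- rep(1, nrow(pairs))
    scale_used <- NA_real_
  } else {
    scale_used <- if (identical(scale, "auto")) {
      if (nrow(pairs)) median(as.double(gaps)) else NA_real_
    } else {
      stopifnot(is_scalar_num(scale), scale > 0)
      as.double(scale)
    }
    weights <- pmin(1, scale_used / as.double(gaps))
  }
  structure(list(pairs = pairs, weights = as.double(weights),
                 form = form, scale_used = scale_used),
            class = "fusion_weights")
}

#' @export
print.fusion_weights <- function(x, ...) {
  cat(sprintf("fusion_weights: %d adjacent pairs, form = %s, scale = %s\n",
              nrow(x$pairs), x$form, format(x$scale_used)))
  invisible(x)
}
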