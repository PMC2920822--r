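#' Ordered probe annotation table
#'
#' A `probe_map` holds the genomic annotation of the array probes and defines
#' the adjacency used by the fusion constraints: probes are kept sorted by
#' (chromosome, position) and adjacent probes are fused only when they lie on
#' the same chromosomal arm.
#'
#' @param probe_id character vector of unique probe labels.
#' @param chromosome character vector of chromosome labels.
#' @param position 1-based base-pair positions, strictly increasing within a
#'   chromosome after sorting.
#' @param arm chromosomal arm, `"p"` or `"q"`; within a chromosome all p-arm
#'   probes must precede all q-arm probes.
#'
#' @return A `data.frame` of class `probe_map` with columns `probe_id`,
#'   `chromosome`, `position`, `arm`, sorted by (chromosome, position).
#' @export
probe_map <- function(probe_id, chromosome, position, arm) {
  pm <- data.frame(probe_id = as.character(probe_id),
                   chromosome = as.character(chromosome),
                   position = as.integer(position),
                   arm = as.character(arm),
                   stringsAsFactors = FALSE)
  ord <- order(chrom_rank(pm$chromosome), pm$position, method = "radix")
  pm <- pm[ord, , drop = FALSE]
  rownames(pm) <- NULL
  class(pm) <- c("probe_map", "data.frame")
  validate_probe_map(pm)
  pm
}

#' Validate a probe map
#'
#' Checks the structural invariants: unique probe ids, strictly increasing
#' positions within each chromosome (duplicate positions are rejected, not
#' resolved), arms restricted to p/q with all p before all q.
#'
#' @param pm a `probe_map`.
#' @return `pm`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_probe_map <- function(pm) {
  stopifnot(is.data.frame(pm))
  need <- c("probe_id", "chromosome", "position", "arm")
  if (!all(need %in% names(pm))) {
    stop("probe map must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(pm$probe_id)) {
    stop("duplicate probe_id in probe map", call. = FALSE)
  }
  if (any(is.na(pm$position)) || any(pm$position < 1)) {
    stop("probe positions must be positive 1-based integers", call. = FALSE)
  }
  if (!all(pm$arm %in% c("p", "q"))) {
    stop("arm must be 'p' or 'q'", call. = FALSE)
  }
  for (chr in unique(pm$chromosome)) {
    sel <- pm$chromosome == chr
    pos <- pm$position[sel]
    if (any(diff(pos) <= 0)) {
      stop("positions on chromosome ", chr,
           " are not strictly increasing (duplicate positions are rejected)",
           call. = FALSE)
    }
    a <- pm$arm[sel]
    if (any(diff(match(a, c("p", "q"))) < 0)) {
      stop("on chromosome ", chr, " all p-arm probes must precede q-arm probes",
           call. = FALSE)
    }
  }
  invisible(pm)
}

#' @export
print.probe_map <- function(x, ...) {
  cat(sprintf("probe_map: %d probes on %d chromosome(s)\n",
              nrow(x), length(unique(x$chromosome))))
  NextMethod()
}
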