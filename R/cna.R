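#' Call discrete CNAs from a cluster centroid
#'
#' A deliberately simple threshold-plus-minimum-run caller: maximal runs of
#' at least `min_probes` consecutive probes within one chromosomal arm whose
#' centroid values all exceed `+amp_threshold` (gain) or all fall below
#' `-amp_threshold` (loss).  Each run becomes one call with
#' `mean_amplitude` the mean centroid value over the run.  The caller is
#' pluggable; any segmentation of the centroid could replace it.
#'
#' @param centroid numeric vector over probes (see [centroid()]).
#' @param probe_map the matching [probe_map()].
#' @param amp_threshold positive amplitude threshold in log2-ratio units
#'   (default 0.2, a typical aCGH noise floor).
#' @param min_probes minimum run length in probes (default 5).
#' @param node_id,n_samples optional provenance: the cluster the centroid
#'   summarizes and its size.
#' @return A `data.frame` of class `cna_calls` with columns `chromosome`,
#'   `start_probe`, `end_probe` (1-based, inclusive, indices into
#'   `probe_map`), `start_bp`, `end_bp`, `direction` (`gain`/`loss`),
#'   `mean_amplitude`, `n_probes`, `node_id`, `n_samples`.  Zero rows when
#'   nothing exceeds the threshold.
#' @export
call_cnas <- function(centroid, probe_map, amp_threshold = 0.2,
                      min_probes = 5L, node_id = NA_character_,
                      n_samples = NA_integer_) {
  validate_probe_map(probe_map)
  stopifnot(length(centroid) == nrow(probe_map),
            is_scalar_num(amp_threshold), amp_threshold > 0,
            is_count(min_probes))
  state <- ifelse(centroid > amp_threshold, 1L,
                  ifelse(centroid < -amp_threshold, -1L, 0L))
  block <- paste(probe_map$chromosome, probe_map$arm)
  out <- list()
  for (bl in unique(block)) {
    idx <- which(block == bl)
    r <- rle(state[idx])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values != 0L & r$lengths >= min_probes
    for (k in which(keep)) {
      lo <- idx[starts[k]]; hi <- idx[ends[k]]
      out[[length(out) + 1L]] <- data.frame(
        chromosome = probe_map$chromosome[lo],
        start_probe = lo, end_probe = hi,
        start_bp = probe_map$position[lo], end_bp = probe_map$position[hi],
        direction = if (r$values[k] > 0L) "gain" else "loss",
        mean_amplitude = mean(centroid[lo:hi]),
        n_probes = hi - lo + 1L,
        node_id = node_id, n_samples = n_samples,
        stringsAsFactors = FALSE)
    }
  }
  calls <- if (length(out)) do.call(rbind, out) else data.frame(
    chromosome = character(0), start_probe = integer(0),
    end_probe = integer(0), start_bp = integer(0), end_bp = integer(0),
    direction = character(0), mean_amplitude = numeric(0),
    n_probes = integer(0), node_id = character(0), n_samples = integer(0),
    stringsAsFactors = FALSE)
  calls <- calls[order(chrom_rank(calls$chromosome), calls$start_probe), ,
                 drop = FALSE]
  rownames(calls) <- NULL
  class(calls) <- c("cna_calls", "data.frame")
  calls
}

#' Write CNA calls as BED or SEG
#'
#' BED output is 0-based half-open; SEG output is 1-based inclusive with
#' columns ID (the cluster/node id), chrom, loc.start, loc.end, num.mark,
#' seg.mean.  An empty call set produces a header-only file.
#'
#' @param calls a [call_cnas()] result (rows from several nodes may be
#'   concatenated with `rbind`).
#' @param path output file path.
#' @param format `"bed"` or `"seg"`.
#' @param header optional `#`-prefixed provenance lines.
#' @return `calls`, invisibly.
#' @export
write_cna_calls <- function(calls, path, format = c("bed", "seg"),
                            header = NULL) {
  format <- match.arg(format)
  stopifnot(is.data.frame(calls))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  if (format == "bed") {
    writeLines("#chrom\tchromStart\tchromEnd\tname\tscore\tstrand", con)
    if (nrow(calls)) {
      name <- paste(ifelse(is.na(calls$node_id), "cna", calls$node_id),
                    calls$direction, sep = "|")
      writeLines(paste(calls$chromosome, calls$start_bp - 1L, calls$end_bp,
                       name, format_num(calls$mean_amplitude), ".",
                       sep = "\t"), con)
    }
  } else {
    writeLines("ID\tchrom\tloc.start\tloc.end\tnum.mark\tseg.mean", con)
    if (nrow(calls)) {
      writeLines(paste(ifelse(is.na(calls$node_id), "cna", calls$node_id),
                       calls$chromosome, calls$start_bp, calls$end_bp,
                       calls$n_probes, format_num(calls$mean_amplitude),
                       sep = "\t"), con)
    }
  }
  invisible(calls)
}

format_num <- function(x) {
  vapply(x, function(v) format(v, digits = 15, scientific = FALSE,
                               trim = TRUE), "")
}

#' Pairwise CNA co-occurrence by Fisher's exact test
#'
#' For every unordered pair of CNAs, builds the 2x2 contingency table of
#' joint sample membership and reports the one-sided (enrichment) Fisher
#' exact p-value: small values mean the two CNAs co-occur in the same
#' samples more often than their background frequencies predict.  A CNA
#' present in all samples or in none has a fixed margin; such pairs are
#' reported with `p_value = 1` and `degenerate = TRUE`.
#'
#' @param assignments logical matrix, samples in rows, CNAs in columns
#'   (column names are the CNA identifiers); `TRUE` when the sample belongs
#'   to the cluster carrying the CNA.
#' @return A `data.frame` with columns `cna_a`, `cna_b`, `n_both`, `n_a_only`,
#'   `n_b_only`, `n_neither`, `direction` (`enriched`/`depleted` relative to
#'   independence), `p_value`, `degenerate`.
#' @export
cooccurrence <- function(assignments) {
  assignments <- as.matrix(assignments)
  if (is.numeric(assignments)) assignments <- assignments != 0
  stopifnot(is.logical(assignments))
  if (ncol(assignments) < 2L) stop("need at least 2 CNAs", call. = FALSE)
  if (nrow(assignments) < 1L) stop("need at least 1 sample", call. = FALSE)
  ids <- colnames(assignments) %||% paste0("cna", seq_len(ncol(assignments)))
  n <- nrow(assignments)
  combs <- utils::combn(ncol(assignments), 2L)
  out <- lapply(seq_len(ncol(combs)), function(k) {
    i <- combs[1L, k]; j <- combs[2L, k]
    a <- assignments[, i]; b <- assignments[, j]
    n11 <- sum(a & b); n10 <- sum(a & !b); n01 <- sum(!a & b)
    n00 <- n - n11 - n10 - n01
    degenerate <- sum(a) %in% c(0L, n) || sum(b) %in% c(0L, n)
    pv <- if (degenerate) 1 else
      fisher.test(matrix(c(n11, n01, n10, n00), 2L),
                  alternative = "greater")$p.value
    expected <- sum(a) * sum(b) / n
    data.frame(cna_a = ids[i], cna_b = ids[j],
               n_both = n11, n_a_only = n10, n_b_only = n01, n_neither = n00,
               direction = if (n11 >= expected) "enriched" else "depleted",
               p_value = pv, degenerate = degenerate,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a co-occurrence table as TSV
#'
#' @param tab a [cooccurrence()] result.
#' @param path output path.
#' @param header optional `#`-prefixed provenance lines.
#' @return `tab`, invisibly.
#' @export
write_cooccurrence <- function(tab, path, header = NULL) {
  write_tsv_with_header(tab, path, header)
  invisible(tab)
}

#' CNA sample-assignment matrix from partition trees
#'
#' Calls CNAs on the centroid of every non-root cluster of each tree and
#' returns (i) the concatenated calls, one CNA id per call, and (ii) the
#' logical sample-by-CNA membership matrix used by [cooccurrence()]: a
#' sample carries a CNA when it belongs to the cluster whose centroid showed
#' the event.
#'
#' @param X the [profile_matrix()] the trees were built from (all
#'   chromosomes).
#' @param trees list of `partition_tree` objects (see [build_trees()]).
#' @param amp_threshold,min_probes passed to [call_cnas()].
#' @return List with `calls` (a `cna_calls` data frame with a `cna_id`
#'   column) and `assignments` (logical matrix samples x CNAs).
#' @export
cna_assignment_matrix <- function(X, trees, amp_threshold = 0.2,
                                  min_probes = 5L) {
  stopifnot(inherits(X, "profile_matrix"))
  by_chrom <- split_by_chromosome(X)
  all_calls <- list()
  cols <- list()
  for (tree in trees) {
    chrom_X <- by_chrom[[tree$chromosome]]
    if (is.null(chrom_X)) {
      stop("tree chromosome ", tree$chromosome, " absent from profiles",
           call. = FALSE)
    }
    for (node in tree_nodes(tree)) {
      if (node$depth == 0L) next  # root cluster = whole cohort, not a CNA group
      cen <- centroid(chrom_X, match(node$sample_ids, chrom_X$sample_ids))
      calls <- call_cnas(cen, chrom_X$probe_map, amp_threshold, min_probes,
                         node_id = node$node_id,
                         n_samples = length(node$sample_ids))
      if (!nrow(calls)) next
      calls$cna_id <- sprintf("%s:%s:%d-%d", calls$node_id, calls$direction,
                              calls$start_bp, calls$end_bp)
      all_calls[[length(all_calls) + 1L]] <- calls
      for (k in seq_len(nrow(calls))) {
        cols[[calls$cna_id[k]]] <- X$sample_ids %in% node$sample_ids
      }
    }
  }
  calls <- if (length(all_calls)) do.call(rbind, all_calls) else NULL
  assignments <- if (length(cols)) {
    mat <- do.call(cbind, cols)
    rownames(mat) <- X$sample_ids
    mat
  } else NULL
  list(calls = calls, assignments = assignments)
}
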