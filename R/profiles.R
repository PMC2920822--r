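#' Probe-level log-ratio matrix tied to a probe map
#'
#' A `profile_matrix` couples an n-samples-by-p-probes matrix of log2 ratios
#' with the `probe_map` describing its columns.  Values must be complete
#' (missing entries are resolved at read time, see [read_profiles()]).
#'
#' @param values numeric matrix, samples in rows, probes in columns.
#' @param probe_map a [probe_map()] with one row per column of `values`.
#' @param sample_ids character vector of sample labels; defaults to
#'   `rownames(values)`.
#' @return An object of class `profile_matrix` with fields `values`,
#'   `probe_map`, `sample_ids`.
#' @export
profile_matrix <- function(values, probe_map, sample_ids = rownames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  validate_probe_map(probe_map)
  if (ncol(values) != nrow(probe_map)) {
    stop("profile matrix has ", ncol(values), " columns but probe map has ",
         nrow(probe_map), " probes", call. = FALSE)
  }
  if (is.null(sample_ids)) sample_ids <- sprintf("S%03d", seq_len(nrow(values)))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(values)) {
    stop("sample_ids length does not match number of rows", call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids", call. = FALSE)
  if (anyNA(values)) stop("profile matrix contains missing values", call. = FALSE)
  dimnames(values) <- list(sample_ids, probe_map$probe_id)
  structure(list(values = values, probe_map = probe_map,
                 sample_ids = sample_ids),
            class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("profile_matrix: %d samples x %d probes (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$probe_map$chromosome), collapse = ", ")))
  invisible(x)
}

#' @export
dim.profile_matrix <- function(x) dim(x$values)

#' Read a cohort of aCGH profiles from delimited text
#'
#' Reads a tab-delimited log-ratio matrix (first column sample id, remaining
#' columns one per probe, header row of probe ids) together with a probe
#' annotation table (columns `probe_id`, `chromosome`, `position`, `arm`).
#' Probes are reordered by genomic position, so shuffled input columns or
#' annotation rows produce the identical object.
#'
#' Missing-value policy (`"median-impute"`, the default): probes missing in
#' more than `max_missing_frac` of samples are dropped; remaining missing
#' entries are replaced by the per-probe median of the observed samples.
#' `"drop"` removes every probe with any missing entry; `"fail"` errors on
#' any missing entry.
#'
#' @param matrix_path path to the TSV value matrix.
#' @param annotation_path path to the TSV probe annotation.
#' @param missing_policy one of `"median-impute"`, `"drop"`, `"fail"`.
#' @param max_missing_frac fraction of missing samples above which a probe is
#'   dropped under `"median-impute"` (default 0.2).
#' @return A [profile_matrix()].
#' @export
read_profiles <- function(matrix_path, annotation_path,
                          missing_policy = c("median-impute", "drop", "fail"),
                          max_missing_frac = 0.2) {
  missing_policy <- match.arg(missing_policy)
  ann <- read.delim(annotation_path, stringsAsFactors = FALSE,
                    comment.char = "#", check.names = FALSE)
  need <- c("probe_id", "chromosome", "position", "arm")
  if (!all(need %in% names(ann))) {
    stop("annotation must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  mat <- read.delim(matrix_path, stringsAsFactors = FALSE,
                    comment.char = "#", check.names = FALSE)
  sample_ids <- as.character(mat[[1L]])
  values <- as.matrix(mat[, -1L, drop = FALSE])
  storage.mode(values) <- "double"
  if (!setequal(colnames(values), ann$probe_id) ||
      ncol(values) != nrow(ann)) {
    stop("probe columns of the matrix do not match the annotation probe set",
         call. = FALSE)
  }
  pm <- probe_map(ann$probe_id, ann$chromosome, ann$position, ann$arm)
  values <- values[, pm$probe_id, drop = FALSE]

  miss_frac <- colMeans(is.na(values))
  if (missing_policy == "fail" && any(miss_frac > 0)) {
    stop("missing values present and missing_policy = 'fail'", call. = FALSE)
  }
  drop <- switch(missing_policy,
                 "median-impute" = miss_frac > max_missing_frac,
                 "drop"          = miss_frac > 0,
                 "fail"          = rep(FALSE, ncol(values)))
  if (any(drop)) {
    values <- values[, !drop, drop = FALSE]
    pm <- pm[!drop, , drop = FALSE]
    class(pm) <- c("probe_map", "data.frame")
  }
  if (anyNA(values)) {
    med <- matrixStats::colMedians(values, na.rm = TRUE)
    idx <- which(is.na(values), arr.ind = TRUE)
    values[idx] <- med[idx[, 2L]]
  }
  profile_matrix(values, pm, sample_ids)
}

#' Write a cohort to the TSV formats read by [read_profiles()]
#'
#' @param x a [profile_matrix()].
#' @param matrix_path,annotation_path output paths.
#' @param header optional character vector of `#`-prefixed provenance lines
#'   written at the top of each file.
#' @return `x`, invisibly.
#' @export
write_profiles <- function(x, matrix_path, annotation_path, header = NULL) {
  stopifnot(inherits(x, "profile_matrix"))
  write_tsv_with_header(
    data.frame(sample_id = x$sample_ids, x$values, check.names = FALSE),
    matrix_path, header)
  write_tsv_with_header(as.data.frame(x$probe_map), annotation_path, header)
  invisible(x)
}

write_tsv_with_header <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Restrict a profile matrix to a subset of samples
#'
#' @param x a [profile_matrix()].
#' @param samples integer/logical index or character sample ids.
#' @return A [profile_matrix()] over the selected samples.
#' @export
subset_samples <- function(x, samples) {
  stopifnot(inherits(x, "profile_matrix"))
  if (is.character(samples)) samples <- match(samples, x$sample_ids)
  profile_matrix(x$values[samples, , drop = FALSE], x$probe_map,
                 x$sample_ids[samples])
}

#' Split a cohort by chromosome
#'
#' The partitioning algorithm runs on one chromosome at a time; this returns
#' one `profile_matrix` per chromosome, in genomic order.
#'
#' @param x a [profile_matrix()].
#' @return Named list of [profile_matrix()] objects.
#' @export
split_by_chromosome <- function(x) {
  stopifnot(inherits(x, "profile_matrix"))
  chroms <- unique(x$probe_map$chromosome)
  out <- lapply(chroms, function(chr) {
    sel <- x$probe_map$chromosome == chr
    pm <- x$probe_map[sel, , drop = FALSE]
    class(pm) <- c("probe_map", "data.frame")
    profile_matrix(x$values[, sel, drop = FALSE], pm, x$sample_ids)
  })
  names(out) <- chroms
  out
}
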