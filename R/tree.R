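#' Parameters for the iterative partitioning tree
#'
#' The three stopping criteria: a group is split only if it contains more
#' than `min_group_size` samples, the split does not exceed `max_depth`, and
#' the split's permutation p-value is at most `p_threshold`.
#'
#' @param min_group_size split only groups larger than this (default 5).
#' @param max_depth maximum tree depth (default 3; the root is depth 0).
#' @param p_threshold per-split significance threshold (default 0.1); the
#'   centroid-distance statistic is not directly optimized by the
#'   classifier, so the permutation p-values run conservative.
#' @param fused a [fused_lasso_params()]; its `seed` is the tree root seed.
#' @param n_perm permutations per split test (default 1000).
#' @return A list of class `tree_params`.
#' @export
tree_params <- function(min_group_size = 5L, max_depth = 3L, p_threshold = 0.1,
                        fused = fused_lasso_params(), n_perm = 1000L) {
  stopifnot(is_count(min_group_size), is_count(max_depth),
            is_scalar_num(p_threshold), p_threshold > 0, p_threshold <= 1,
            inherits(fused, "fused_lasso_params"), is_count(n_perm))
  structure(list(min_group_size = as.integer(min_group_size),
                 max_depth = as.integer(max_depth),
                 p_threshold = as.double(p_threshold),
                 fused = fused, n_perm = as.integer(n_perm)),
            class = "tree_params")
}

new_partition_node <- function(node_id, sample_ids, depth, seed,
                               separator = NULL, significance = NULL,
                               children = list(), stop_reason = NA_character_,
                               failure_message = NULL) {
  structure(list(node_id = node_id, sample_ids = sample_ids,
                 depth = as.integer(depth), seed = as.integer(seed),
                 separator = separator, significance = significance,
                 children = children, stop_reason = stop_reason,
                 failure_message = failure_message),
            class = "partition_node")
}

#' Build the per-chromosome partition tree
#'
#' Recursively bipartitions the cohort with [mmc_partition()], making each
#' node's separator orthogonal to the separators of all its ancestors (so
#' successive splits explore new directions of variation, in the spirit of
#' principal components).  A candidate split is kept only when the node has
#' more than `min_group_size` samples, lies above `max_depth`, and its
#' permutation p-value is at most `p_threshold`; otherwise the node becomes a
#' leaf with its `stop_reason` recorded (`too_small`, `max_depth`,
#' `not_significant`, or `failure` if the QP or the test errored).  A trivial
#' clustering (all samples on one side) is recorded as `not_significant`.
#'
#' Per-node seeds are derived deterministically from the root seed
#' (`params$fused$seed`) and the node path, so sibling subtrees have
#' independent but reproducible randomness.
#'
#' @param X a [profile_matrix()] restricted to a single chromosome, with at
#'   least 2 samples.
#' @param params a [tree_params()].
#' @param weights optional [compute_fusion_weights()] result; computed with
#'   defaults when `NULL`.
#' @return An object of class `partition_tree`: fields `root`
#'   (`partition_node`), `chromosome`, `n_samples`, `params`.
#' @export
build_tree <- function(X, params = tree_params(), weights = NULL) {
  stopifnot(inherits(X, "profile_matrix"), inherits(params, "tree_params"))
  chroms <- unique(X$probe_map$chromosome)
  if (length(chroms) != 1L) {
    stop("build_tree expects a single chromosome; use split_by_chromosome()",
         call. = FALSE)
  }
  if (nrow(X$values) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (is.null(weights)) weights <- compute_fusion_weights(X$probe_map)
  root_seed <- params$fused$seed

  grow <- function(sample_idx, depth, path, ancestors) {
    node_id <- paste0(chroms, ":", path)
    seed <- derive_seed(root_seed, path)
    ids <- X$sample_ids[sample_idx]
    leaf <- function(reason, separator = NULL, significance = NULL, msg = NULL) {
      new_partition_node(node_id, ids, depth, seed, separator, significance,
                         list(), reason, msg)
    }
    if (length(sample_idx) <= params$min_group_size) return(leaf("too_small"))
    if (depth >= params$max_depth) return(leaf("max_depth"))

    res <- tryCatch({
      sub <- subset_samples(X, sample_idx)
      node_params <- params$fused
      node_params$seed <- seed
      mmc <- mmc_partition(sub, node_params, weights, ancestors)
      if (mmc$trivial) {
        list(kind = "leaf", node = leaf("not_significant", mmc$separator))
      } else {
        sig <- split_significance(sub, mmc$separator,
                                  n_perm = params$n_perm, seed = seed)
        if (sig$p_value > params$p_threshold) {
          list(kind = "leaf",
               node = leaf("not_significant", mmc$separator, sig))
        } else {
          list(kind = "split", mmc = mmc, sig = sig)
        }
      }
    }, error = function(e) {
      list(kind = "leaf",
           node = leaf("failure", msg = conditionMessage(e)))
    })
    if (res$kind == "leaf") return(res$node)

    sep <- res$mmc$separator
    anc <- c(ancestors, list(sep$beta))
    pos <- sample_idx[sep$labels > 0]
    neg <- sample_idx[sep$labels < 0]
    children <- list(grow(pos, depth + 1L, paste0(path, "p"), anc),
                     grow(neg, depth + 1L, paste0(path, "m"), anc))
    new_partition_node(node_id, ids, depth, seed, sep, res$sig,
                       children, "split")
  }

  root <- grow(seq_along(X$sample_ids), 0L, "0", list())
  structure(list(root = root, chromosome = chroms,
                 n_samples = length(X$sample_ids), params = params),
            class = "partition_tree")
}

#' Build one partition tree per chromosome
#'
#' @param X a [profile_matrix()] (any number of chromosomes).
#' @param params a [tree_params()].
#' @return Named list of [build_tree()] results, one per chromosome.
#' @export
build_trees <- function(X, params = tree_params()) {
  lapply(split_by_chromosome(X), build_tree, params = params)
}

#' Flatten a partition tree into a list of nodes
#'
#' @param tree a `partition_tree` (or a `partition_node`).
#' @return List of `partition_node` objects in preorder.
#' @export
tree_nodes <- function(tree) {
  node <- if (inherits(tree, "partition_tree")) tree$root else tree
  out <- list(node)
  for (child in node$children) out <- c(out, tree_nodes(child))
  out
}

#' Per-node summary table
#'
#' @param tree a `partition_tree`.
#' @return A `data.frame` with one row per node: `node_id`, `depth`,
#'   `n_samples`, `p_value`, `stop_reason`.
#' @export
tree_summary <- function(tree) {
  nodes <- tree_nodes(tree)
  data.frame(
    node_id = vapply(nodes, function(n) n$node_id, ""),
    depth = vapply(nodes, function(n) n$depth, 0L),
    n_samples = vapply(nodes, function(n) length(n$sample_ids), 0L),
    p_value = vapply(nodes, function(n)
      if (is.null(n$significance)) NA_real_ else n$significance$p_value, 0),
    stop_reason = vapply(nodes, function(n) n$stop_reason, ""),
    stringsAsFactors = FALSE)
}

#' Samples belonging to a tree node
#'
#' @param tree a `partition_tree`.
#' @param node_id a node id as shown in [tree_summary()].
#' @return Character vector of sample ids.
#' @export
node_members <- function(tree, node_id) {
  for (n in tree_nodes(tree)) if (n$node_id == node_id) return(n$sample_ids)
  stop("no node with id ", node_id, call. = FALSE)
}

## ---- serialization ----------------------------------------------------

node_to_list <- function(node) {
  list(node_id = jsonlite::unbox(node$node_id),
       sample_ids = as.character(node$sample_ids),
       depth = jsonlite::unbox(node$depth),
       seed = jsonlite::unbox(node$seed),
       separator = if (is.null(node$separator)) NULL else list(
         beta = node$separator$beta,
         bias = jsonlite::unbox(node$separator$bias),
         labels = if (is.null(node$separator$labels)) NULL else
           as.integer(node$separator$labels),
         objective = jsonlite::unbox(node$separator$objective)),
       significance = if (is.null(node$significance)) NULL else list(
         observed_distance = jsonlite::unbox(node$significance$observed_distance),
         null_mean = jsonlite::unbox(node$significance$null_mean),
         null_sd = jsonlite::unbox(node$significance$null_sd),
         p_value = jsonlite::unbox(node$significance$p_value),
         n_perm = jsonlite::unbox(node$significance$n_perm),
         degenerate = jsonlite::unbox(node$significance$degenerate)),
       stop_reason = jsonlite::unbox(node$stop_reason),
       failure_message = if (is.null(node$failure_message)) NULL else
         jsonlite::unbox(node$failure_message),
       children = lapply(node$children, node_to_list))
}

node_from_list <- function(lst) {
  sep <- if (is.null(lst$separator)) NULL else
    new_separator(lst$separator$beta, lst$separator$bias,
                  labels = if (is.null(lst$separator$labels)) NULL else
                    as.integer(lst$separator$labels),
                  objective = lst$separator$objective)
  sig <- if (is.null(lst$significance)) NULL else
    structure(list(observed_distance = lst$significance$observed_distance,
                   null_mean = lst$significance$null_mean,
                   null_sd = lst$significance$null_sd,
                   p_value = lst$significance$p_value,
                   n_perm = as.integer(lst$significance$n_perm),
                   degenerate = lst$significance$degenerate),
              class = "significance_result")
  new_partition_node(lst$node_id, as.character(lst$sample_ids), lst$depth,
                     lst$seed, sep, sig,
                     lapply(lst$children, node_from_list),
                     lst$stop_reason, lst$failure_message)
}

#' Write / read a partition tree as JSON
#'
#' The JSON document is lossless: numeric fields are written with 17
#' significant digits so that `read_tree(write_tree(tree))` reproduces every
#' field (including p-values) to full double precision.
#'
#' @param tree a `partition_tree`.
#' @param path output (input) file path.
#' @param provenance optional named list stored under `"provenance"`.
#' @return `write_tree` returns `tree` invisibly; `read_tree` returns the
#'   `partition_tree`.
#' @export
write_tree <- function(tree, path, provenance = NULL) {
  stopifnot(inherits(tree, "partition_tree"))
  doc <- list(
    format = jsonlite::unbox("cnamargin-partition-tree"),
    chromosome = jsonlite::unbox(tree$chromosome),
    n_samples = jsonlite::unbox(tree$n_samples),
    params = list(
      min_group_size = jsonlite::unbox(tree$params$min_group_size),
      max_depth = jsonlite::unbox(tree$params$max_depth),
      p_threshold = jsonlite::unbox(tree$params$p_threshold),
      n_perm = jsonlite::unbox(tree$params$n_perm),
      s1 = jsonlite::unbox(tree$params$fused$s1),
      s2 = jsonlite::unbox(tree$params$fused$s2),
      max_iter = jsonlite::unbox(tree$params$fused$max_iter),
      seed = jsonlite::unbox(tree$params$fused$seed)),
    provenance = provenance,
    root = node_to_list(tree$root))
  json <- jsonlite::toJSON(doc, digits = I(17), null = "null", pretty = TRUE)
  writeLines(json, path)
  invisible(tree)
}

#' @rdname write_tree
#' @export
read_tree <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  if (!identical(doc$format, "cnamargin-partition-tree")) {
    stop("not a cnamargin partition-tree file: ", path, call. = FALSE)
  }
  params <- tree_params(
    min_group_size = doc$params$min_group_size,
    max_depth = doc$params$max_depth,
    p_threshold = doc$params$p_threshold,
    fused = fused_lasso_params(doc$params$s1, doc$params$s2,
                               doc$params$max_iter, doc$params$seed),
    n_perm = doc$params$n_perm)
  structure(list(root = node_from_list(doc$root),
                 chromosome = doc$chromosome,
                 n_samples = as.integer(doc$n_samples),
                 params = params),
            class = "partition_tree")
}

#' @export
print.partition_tree <- function(x, ...) {
  cat(sprintf("partition_tree: chromosome %s, %d samples\n",
              x$chromosome, x$n_samples))
  show <- function(node, indent) {
    p <- if (is.null(node$significance)) "" else
      sprintf(", p = %.3g", node$significance$p_value)
    cat(sprintf("%s%s: n = %d [%s%s]\n", strrep("  ", indent), node$node_id,
                length(node$sample_ids), node$stop_reason, p))
    for (ch in node$children) show(ch, indent + 1L)
  }
  show(x$root, 1L)
  invisible(x)
}
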