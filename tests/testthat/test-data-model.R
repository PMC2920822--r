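## Readers/writers and the core containers.

write_cohort_files <- function(values, ann, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  mat_path <- file.path(dir, "matrix.tsv")
  ann_path <- file.path(dir, "annotation.tsv")
  df <- data.frame(sample_id = rownames(values), values, check.names = FALSE)
  write.table(df, mat_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(ann, ann_path, sep = "\t", quote = FALSE, row.names = FALSE)
  list(matrix = mat_path, annotation = ann_path)
}

demo_annotation <- function() {
  data.frame(probe_id = c("P1", "P2", "P3", "P4"),
             chromosome = "1", position = c(100L, 200L, 300L, 400L),
             arm = c("p", "p", "q", "q"), stringsAsFactors = FALSE)
}

test_that("reading a complete cohort round-trips and sorts probes by position", {
  ann <- demo_annotation()
  values <- matrix(seq(0.1, 1.2, by = 0.1), 3, 4,
                   dimnames = list(c("A", "B", "C"), ann$probe_id))
  paths <- write_cohort_files(values, ann)
  X <- read_profiles(paths$matrix, paths$annotation)
  expect_s3_class(X, "profile_matrix")
  expect_identical(dim(X), c(3L, 4L))
  expect_identical(X$sample_ids, c("A", "B", "C"))
  expect_identical(X$probe_map$probe_id, ann$probe_id)
  expect_equal(unname(X$values), unname(values))

  ## shuffled annotation rows and matrix columns give the identical object
  shuf <- c(3, 1, 4, 2)
  paths2 <- write_cohort_files(values[, shuf], ann[shuf, ])
  X2 <- read_profiles(paths2$matrix, paths2$annotation)
  expect_identical(X2$values, X$values)
  expect_identical(as.data.frame(X2$probe_map), as.data.frame(X$probe_map))
})

test_that("missing-value policy drops saturated probes and imputes the rest", {
  ann <- demo_annotation()
  values <- matrix(c(0.1, 0.2, 0.3, 0.4, 0.5,   # P1
                     0.5, NA,  0.9, 0.6, 0.8,   # P2: 1/5 missing -> impute
                     NA,  NA,  NA,  NA,  NA,    # P3: all missing -> drop
                     1.0, 1.1, 1.2, 1.3, 1.4),  # P4
                   5, 4, dimnames = list(LETTERS[1:5], ann$probe_id))
  paths <- write_cohort_files(values, ann)
  X <- read_profiles(paths$matrix, paths$annotation)
  expect_identical(X$probe_map$probe_id, c("P1", "P2", "P4"))
  ## the missing P2 entry equals the median of the observed values
  expect_equal(X$values["B", "P2"], median(c(0.5, 0.9, 0.6, 0.8)))
  expect_false(anyNA(X$values))

  expect_error(read_profiles(paths$matrix, paths$annotation,
                             missing_policy = "fail"), "missing")
  Xd <- read_profiles(paths$matrix, paths$annotation, missing_policy = "drop")
  expect_identical(Xd$probe_map$probe_id, c("P1", "P4"))
  ## with 3 samples a single missing entry exceeds the 20% cap: dropped
  small <- values[1:3, ]
  paths3 <- write_cohort_files(small, ann)
  X3 <- read_profiles(paths3$matrix, paths3$annotation)
  expect_identical(X3$probe_map$probe_id, c("P1", "P4"))
})

test_that("malformed inputs are rejected with format errors", {
  ann <- demo_annotation()
  values <- matrix(rnorm(12), 3, 4,
                   dimnames = list(c("A", "B", "C"), c("P1", "P2", "P3", "PX")))
  paths <- write_cohort_files(values, ann)  # PX not in annotation
  expect_error(read_profiles(paths$matrix, paths$annotation), "probe")

  dup <- ann; dup$position[2] <- 100L  # duplicate position on chr 1
  values2 <- matrix(rnorm(12), 3, 4,
                    dimnames = list(c("A", "B", "C"), ann$probe_id))
  paths2 <- write_cohort_files(values2, dup)
  expect_error(read_profiles(paths2$matrix, paths2$annotation),
               "strictly increasing")

  expect_error(probe_map("P1", "1", 100, "z"), "arm")
  expect_error(probe_map(c("P1", "P2"), c("1", "1"), c(100, 200), c("q", "p")),
               "precede")
})

test_that("profile TSV writer round-trips through the reader", {
  pm <- make_probe_map(12, "lognormal", seed = 4)
  dat <- generate_dataset(5, pm, noise_sd = 0.2, seed = 4)
  dir <- withr::local_tempdir()
  write_profiles(dat$profiles, file.path(dir, "m.tsv"), file.path(dir, "a.tsv"),
                 header = c("demo", "seed = 4"))
  X <- read_profiles(file.path(dir, "m.tsv"), file.path(dir, "a.tsv"))
  expect_equal(X$values, dat$profiles$values)
  expect_identical(as.data.frame(X$probe_map), as.data.frame(pm))
})

test_that("CNA call output follows BED and SEG coordinate conventions", {
  pm <- probe_map(paste0("P", 1:6), rep("2", 6),
                  c(100L, 150L, 200L, 250L, 300L, 350L), rep("p", 6))
  cen <- c(0.8, 0.8, 0.8, 0, 0, 0)
  calls <- call_cnas(cen, pm, amp_threshold = 0.2, min_probes = 3,
                     node_id = "2:0p", n_samples = 7L)
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$start_bp, 100L)
  expect_identical(calls$end_bp, 200L)

  dir <- withr::local_tempdir()
  bed <- file.path(dir, "calls.bed")
  write_cna_calls(calls, bed, format = "bed")
  lines <- readLines(bed)
  fields <- strsplit(lines[2], "\t")[[1]]
  expect_identical(fields[1:3], c("2", "99", "200"))  # 0-based half-open

  seg <- file.path(dir, "calls.seg")
  write_cna_calls(calls, seg, format = "seg")
  segline <- strsplit(readLines(seg)[2], "\t")[[1]]
  expect_identical(segline[3:4], c("100", "200"))     # 1-based inclusive
  expect_identical(segline[6], "0.8")
  expect_identical(segline[5], "3")

  ## empty call set -> header-only files
  empty <- call_cnas(rep(0, 6), pm)
  for (fmt in c("bed", "seg")) {
    f <- file.path(dir, paste0("empty.", fmt))
    write_cna_calls(empty, f, format = fmt)
    expect_length(readLines(f), 1L)
  }
  expect_error(write_cna_calls(calls, file.path(dir, "x"), format = "gff"))
})

test_that("partition trees round-trip through JSON losslessly", {
  dat <- scenario_dataset("single-event", n_samples = 30, n_probes = 60,
                          seed = 2)
  tree <- build_tree(dat$profiles,
                     tree_params(fused = fused_lasso_params(seed = 2),
                                 n_perm = 50))
  path <- withr::local_tempfile(fileext = ".json")
  write_tree(tree, path)
  back <- read_tree(path)
  expect_identical(back$chromosome, tree$chromosome)
  expect_identical(back$n_samples, tree$n_samples)
  expect_equal(back$params, tree$params)
  n1 <- tree_nodes(tree); n2 <- tree_nodes(back)
  expect_identical(length(n1), length(n2))
  for (k in seq_along(n1)) {
    expect_identical(n2[[k]]$node_id, n1[[k]]$node_id)
    expect_identical(n2[[k]]$sample_ids, n1[[k]]$sample_ids)
    expect_identical(n2[[k]]$depth, n1[[k]]$depth)
    expect_identical(n2[[k]]$stop_reason, n1[[k]]$stop_reason)
    if (!is.null(n1[[k]]$separator)) {
      expect_identical(n2[[k]]$separator$beta, n1[[k]]$separator$beta)
      expect_identical(n2[[k]]$separator$bias, n1[[k]]$separator$bias)
    }
    if (!is.null(n1[[k]]$significance)) {
      ## p-values identical to full double precision
      expect_identical(n2[[k]]$significance$p_value,
                       n1[[k]]$significance$p_value)
    }
  }
})
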