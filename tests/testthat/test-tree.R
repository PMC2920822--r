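## Iterative orthogonal partitioning.

test_that("groups at or below the minimum size become too_small leaves", {
  dat <- scenario_dataset("noise", n_samples = 5, n_probes = 30, seed = 1)
  tree <- build_tree(dat$profiles,
                     tree_params(fused = fused_lasso_params(seed = 1),
                                 n_perm = 50))
  expect_identical(tree$root$stop_reason, "too_small")
  expect_length(tree$root$children, 0)
})

test_that("nodes at the maximum depth become max_depth leaves", {
  dat <- scenario_dataset("arm-loss", n_samples = 30, n_probes = 60, seed = 4)
  tree <- build_tree(dat$profiles,
                     tree_params(max_depth = 1,
                                 fused = fused_lasso_params(seed = 4),
                                 n_perm = 100))
  kids <- tree$root$children
  if (length(kids)) {
    for (k in kids) {
      expect_identical(k$depth, 1L)
      expect_true(k$stop_reason %in%
                    c("max_depth", "too_small", "not_significant"))
    }
    big <- Filter(function(k) length(k$sample_ids) > 5, kids)
    for (k in big) expect_identical(k$stop_reason, "max_depth")
  }
})

test_that("nested planted events are recovered at depths 1 and 2", {
  dat <- scenario_dataset("nested", seed = 5)
  tree <- build_tree(dat$profiles,
                     tree_params(fused = fused_lasso_params(seed = 5),
                                 n_perm = 500))
  n <- 60
  outer_truth <- event_membership(dat$events[[1]], n)
  inner_truth <- event_membership(dat$events[[2]], n)

  expect_identical(tree$root$stop_reason, "split")
  root_labels <- as.integer(dat$profiles$sample_ids %in%
                              tree$root$children[[1]]$sample_ids)
  expect_identical(ari(root_labels, outer_truth), 1)

  ## the child holding the outer carriers must split again on the focal gain
  carrier_child <- if (mean(outer_truth[dat$profiles$sample_ids %in%
                            tree$root$children[[1]]$sample_ids]) > 0.5) {
    tree$root$children[[1]]
  } else {
    tree$root$children[[2]]
  }
  expect_identical(carrier_child$stop_reason, "split")
  inner_ids <- carrier_child$children[[1]]$sample_ids
  sub_truth <- inner_truth[dat$profiles$sample_ids %in%
                             carrier_child$sample_ids]
  sub_labels <- as.integer(carrier_child$sample_ids %in% inner_ids)
  expect_identical(ari(sub_labels, sub_truth), 1)

  ## child separator orthogonal to its ancestor's
  expect_lt(abs(sum(tree$root$separator$beta *
                    carrier_child$separator$beta)), 1e-6)
})

test_that("every tree respects the partition, depth, size and p constraints", {
  trees <- lapply(c(5, 17), function(seed) {
    dat <- scenario_dataset("nested", seed = seed)
    build_tree(dat$profiles,
               tree_params(fused = fused_lasso_params(seed = seed),
                           n_perm = 200))
  })
  trees <- c(trees, lapply(c(3, 11), function(seed) {
    dat <- scenario_dataset("noise", n_samples = 25, n_probes = 50, seed = seed)
    build_tree(dat$profiles,
               tree_params(fused = fused_lasso_params(seed = seed),
                           n_perm = 200))
  }))
  for (tree in trees) {
    check_node <- function(node, ancestors) {
      expect_lte(node$depth, tree$params$max_depth)
      if (identical(node$stop_reason, "split")) {
        expect_gt(length(node$sample_ids), tree$params$min_group_size)
        expect_lte(node$significance$p_value, tree$params$p_threshold)
        kids <- node$children
        expect_length(kids, 2)
        expect_length(intersect(kids[[1]]$sample_ids,
                                kids[[2]]$sample_ids), 0)
        expect_setequal(c(kids[[1]]$sample_ids, kids[[2]]$sample_ids),
                        node$sample_ids)
        for (anc in ancestors) {
          expect_lt(abs(sum(node$separator$beta * anc)), 1e-6)
        }
        for (k in kids) {
          check_node(k, c(ancestors, list(node$separator$beta)))
        }
      } else {
        expect_length(node$children, 0)
      }
    }
    check_node(tree$root, list())
  }
})

test_that("trees are deterministic under the root seed", {
  dat <- scenario_dataset("nested", n_samples = 40, n_probes = 80, seed = 6)
  params <- tree_params(fused = fused_lasso_params(seed = 6), n_perm = 100)
  t1 <- build_tree(dat$profiles, params)
  t2 <- build_tree(dat$profiles, params)
  s1 <- tree_summary(t1); s2 <- tree_summary(t2)
  expect_identical(s1, s2)
})

test_that("per-node seeds differ along the tree but derive from the root", {
  s_root <- cnamargin:::derive_seed(7, "0")
  s_l <- cnamargin:::derive_seed(7, "0p")
  s_r <- cnamargin:::derive_seed(7, "0m")
  expect_true(length(unique(c(s_root, s_l, s_r))) == 3)
  expect_identical(s_l, cnamargin:::derive_seed(7, "0p"))
})
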