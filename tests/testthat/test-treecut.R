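cluster_fixture <- function(K, members, flip, seed, n_ct = 5) {
  spec <- archetype_spec(n_ct, random_archetypes(n_ct, K, seed = seed + 500),
                         members, edge_flip_prob = flip, seed = seed)
  g <- generate_network(spec)
  dm <- pairwise_dissimilarity(g$network)
  list(g = g, dm = dm, tree = hierarchical_linkage(dm))
}

test_that("noiseless planted archetypes are recovered exactly", {
  g <- planted_noiseless(6)
  dm <- pairwise_dissimilarity(g$network)
  cl <- hybrid_tree_cut(hierarchical_linkage(dm), dm)
  expect_identical(cl$n_clusters, 2L)
  expect_true(all(cl$labels > 0))
  expect_equal(mclust::adjustedRandIndex(cl$labels, g$truth), 1)
})

test_that("instances smaller than the minimum cluster size are all unassigned", {
  g <- planted_noiseless(2)          # 4 layers in total, min_cluster_size = 6
  dm <- pairwise_dissimilarity(g$network)
  cl <- hybrid_tree_cut(hierarchical_linkage(dm), dm)
  expect_identical(unname(cl$labels), rep(0L, 4))
  expect_identical(cl$n_clusters, 0L)
})

test_that("labels are equivariant under permuting the layer order", {
  fx <- cluster_fixture(K = 3, members = 7, flip = 0.08, seed = 31)
  base <- hybrid_tree_cut(fx$tree, fx$dm)
  set.seed(8)
  for (r in 1:5) {
    perm <- sample(length(fx$g$network$layers))
    net_p <- build_multiplex(fx$g$network$layers[perm],
                             fx$g$network$cell_types)
    dm_p <- pairwise_dissimilarity(net_p)
    cl_p <- hybrid_tree_cut(hierarchical_linkage(dm_p), dm_p)
    # same partition up to label renaming
    expect_equal(mclust::adjustedRandIndex(
      cl_p$labels[names(base$labels)], base$labels), 1)
  }
})

test_that("every reported cluster satisfies the minimum size", {
  for (seed in 1:6) {
    fx <- cluster_fixture(K = sample(2:4, 1), members = sample(6:10, 1),
                          flip = 0.1, seed = seed)
    cl <- hybrid_tree_cut(fx$tree, fx$dm)
    if (cl$n_clusters > 0)
      expect_gte(min(table(cl$labels[cl$labels > 0])), 6)
  }
})

test_that("tree-cut parameters are validated", {
  fx <- cluster_fixture(K = 2, members = 6, flip = 0, seed = 3)
  expect_error(hybrid_tree_cut(fx$tree, fx$dm, deep_split = 5), "0..4")
  expect_error(hybrid_tree_cut(fx$tree, fx$dm, deep_split = -1), "0..4")
  expect_error(hybrid_tree_cut(fx$tree, fx$dm, min_cluster_size = 0),
               "positive")
})

test_that("the PAM stage governs assignment of outlying layers", {
  # two tight planted groups plus one layer disjoint from both
  g <- planted_noiseless(6)
  ct <- g$network$cell_types
  out_w <- matrix(0, 4, 4, dimnames = list(ct, ct))
  out_w[2, 3] <- 1; out_w[3, 4] <- 1   # edges used by neither archetype
  outlier <- build_layer("outlier", out_w, ct)
  net <- build_multiplex(c(g$network$layers, list(outlier)), ct)
  dm <- pairwise_dissimilarity(net)
  tree <- hierarchical_linkage(dm)
  # without the PAM stage the outlier stays unassigned
  cl0 <- hybrid_tree_cut(tree, dm, pam_stage = FALSE)
  expect_identical(unname(cl0$labels["outlier"]), 0L)
  expect_identical(cl0$n_clusters, 2L)
  # the planted members are labelled identically either way
  cl1 <- hybrid_tree_cut(tree, dm)
  keep <- setdiff(names(cl1$labels), "outlier")
  expect_equal(mclust::adjustedRandIndex(cl1$labels[keep], g$truth[keep]), 1)
})
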