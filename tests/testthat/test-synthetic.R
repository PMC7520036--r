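test_that("generation is bit-identical for a fixed spec", {
  spec <- archetype_spec(5, random_archetypes(5, 2, seed = 2), 4,
                         edge_flip_prob = 0.15, seed = 77)
  g1 <- generate_network(spec)
  g2 <- generate_network(spec)
  expect_identical(g1, g2)
})

test_that("the noiseless limits hold", {
  # sigma = 0, flip = 0: members of an archetype are identical
  g <- planted_noiseless(4)
  net <- g$network
  for (k in 1:2) {
    ids <- names(g$truth)[g$truth == k]
    for (id in ids[-1])
      expect_identical(net$layers[[id]]$weights, net$layers[[ids[1]]]$weights)
  }
  # disjoint archetypes: all cross-archetype dissimilarities are exactly 1
  dm <- pairwise_dissimilarity(net)
  cross <- outer(g$truth, g$truth, "!=")
  expect_identical(unique(dm$values[cross]), 1)
  within <- outer(g$truth, g$truth, "==") & upper.tri(dm$values)
  expect_identical(unique(dm$values[within]), 0)
})

test_that("weights are positive on present edges and lognormal-scaled", {
  spec <- archetype_spec(6, random_archetypes(6, 2, seed = 4), 5,
                         weight_mu = 1, weight_sigma = 0.5,
                         edge_flip_prob = 0.1, seed = 12)
  net <- generate_network(spec)$network
  for (lay in net$layers) {
    w <- lay$weights[lay$weights != 0]
    expect_true(all(w > 0))
  }
})

test_that("the realized flip rate sits within 3-sigma binomial bounds", {
  p <- 0.1
  arch <- matrix(0, 8, 8); arch[1, ] <- 1    # 8 of 64 cells on
  spec <- archetype_spec(8, list(arch), 16, edge_flip_prob = p, seed = 21)
  net <- generate_network(spec)$network
  n_cells <- 16 * 64                          # 1024 Bernoulli draws
  flips <- sum(vapply(net$layers, function(lay)
    sum((lay$weights > 0) != (arch > 0)), numeric(1)))
  bound <- 3 * sqrt(n_cells * p * (1 - p))
  expect_lt(abs(flips - n_cells * p), bound)
})

test_that("spec invariants are enforced", {
  a <- matrix(0, 3, 3); a[1, 2] <- 1
  expect_error(archetype_spec(3, list(a, a), 4), "distinct")
  expect_error(archetype_spec(3, list(matrix(0, 3, 3)), 4), "at least one edge")
  expect_error(archetype_spec(3, list(a), 4, edge_flip_prob = 0.5), "0.5")
  expect_error(archetype_spec(3, list(matrix(1, 2, 2)), 4), "N x N")
  expect_error(archetype_spec(1, list(a), 4), ">= 2")
})

test_that("perturbation moves edges as requested", {
  g <- planted_noiseless(3)
  net <- g$network
  # frac 0: identity
  expect_identical(perturb_network(net, "arch1:m1", 0, seed = 1), net)
  # frac 1 on one layer: its edge set becomes disjoint from the original
  pert <- perturb_network(net, "arch1:m1", 1, seed = 5)
  e_old <- which(net$layers[["arch1:m1"]]$weights > 0)
  e_new <- which(pert$layers[["arch1:m1"]]$weights > 0)
  expect_length(intersect(e_old, e_new), 0)
  expect_length(e_new, length(e_old))
  # all other layers untouched
  for (id in setdiff(pair_ids(net), "arch1:m1"))
    expect_identical(pert$layers[[id]], net$layers[[id]])
  expect_error(perturb_network(net, "nope", 0.5), "unknown pair_id")
  expect_error(perturb_network(net, "arch1:m1", 1.5), "rewire_frac")
})
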