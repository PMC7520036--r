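test_that("self-comparison reports zero change and no exclusives", {
  g <- planted_noiseless(3)
  cmp <- compare_conditions(g$network, g$network)
  expect_identical(unique(cmp$shared$dissimilarity), 0)
  expect_identical(nrow(cmp$shared), length(g$network$layers))
  expect_length(cmp$only_in_a, 0)
  expect_length(cmp$only_in_b, 0)
})

test_that("a fully reversed layer ranks first with dissimilarity 1", {
  ct <- cell_type_set(c("A", "B", "C"))
  w <- matrix(0, 3, 3, dimnames = list(ct, ct)); w["A", "B"] <- 2
  w2 <- matrix(0, 3, 3, dimnames = list(ct, ct)); w2["B", "C"] <- 1
  net_a <- build_multiplex(list(build_layer("flip", w, ct),
                                build_layer("keep", w2, ct)), ct)
  wr <- matrix(0, 3, 3, dimnames = list(ct, ct)); wr["B", "A"] <- 2
  net_b <- build_multiplex(list(build_layer("flip", wr, ct),
                                build_layer("keep", w2, ct)), ct)
  cmp <- compare_conditions(net_a, net_b)
  expect_identical(cmp$shared$pair_id, c("flip", "keep"))
  expect_identical(cmp$shared$dissimilarity, c(1, 0))
  expect_identical(attr(cmp$shared, "order"), "descending")
})

test_that("condition-exclusive pairs are partitioned, not dropped", {
  ct <- cell_type_set(c("A", "B"))
  w <- matrix(c(0, 0, 1, 0), 2)
  mk <- function(id) build_layer(id, w, ct)
  net_a <- build_multiplex(list(mk("both"), mk("a_only")), ct)
  net_b <- build_multiplex(list(mk("both"), mk("b_only")), ct)
  cmp <- compare_conditions(net_a, net_b)
  expect_identical(cmp$shared$pair_id, "both")
  expect_identical(cmp$only_in_a, "a_only")
  expect_identical(cmp$only_in_b, "b_only")
  all_ids <- union(pair_ids(net_a), pair_ids(net_b))
  expect_setequal(c(cmp$shared$pair_id, cmp$only_in_a, cmp$only_in_b), all_ids)

  # antisymmetry of the bookkeeping
  rev <- compare_conditions(net_b, net_a)
  expect_identical(rev$only_in_b, cmp$only_in_a)
  expect_identical(rev$only_in_a, cmp$only_in_b)
  expect_identical(rev$shared$dissimilarity, cmp$shared$dissimilarity)

  # optional convention: exclusives folded in at d = 1
  full <- compare_conditions(net_a, net_b, exclusive_as_max = TRUE)
  expect_identical(nrow(full$shared), 3L)
  expect_identical(full$shared$dissimilarity[full$shared$status != "shared"],
                   c(1, 1))
})

test_that("comparison uses weighted (not binarized) dissimilarity", {
  ct <- cell_type_set(c("A", "B"))
  w1 <- matrix(c(0, 0, 3, 0), 2)
  w2 <- matrix(c(0, 0, 1, 0), 2)
  net_a <- build_multiplex(list(build_layer("p", w1, ct)), ct)
  net_b <- build_multiplex(list(build_layer("p", w2, ct)), ct)
  expect_equal(compare_conditions(net_a, net_b)$shared$dissimilarity, 0.5)
})

test_that("mismatched cell-type sets are refused", {
  ct <- cell_type_set(c("A", "B"))
  net <- build_multiplex(list(build_layer("p", matrix(c(0, 0, 1, 0), 2), ct)), ct)
  ct2 <- cell_type_set(c("B", "A"))
  net2 <- build_multiplex(list(build_layer("p", matrix(c(0, 0, 1, 0), 2), ct2)), ct2)
  expect_error(compare_conditions(net, net2), "same cell types")
})

test_that("median change grows with the rewired fraction", {
  meds <- sapply(c(0, 0.5, 1), function(frac) {
    median(sapply(1:8, function(s) {
      spec <- archetype_spec(5, random_archetypes(5, 2, seed = 9), 4,
                             edge_flip_prob = 0, seed = s)
      net <- generate_network(spec)$network
      pert <- perturb_network(net, "arch1:m1", frac, seed = s + 100)
      cmp <- compare_conditions(net, pert)
      cmp$shared$dissimilarity[cmp$shared$pair_id == "arch1:m1"]
    }))
  })
  expect_true(all(diff(meds) >= 0))
  expect_identical(meds[1], 0)
  expect_identical(meds[3], 1)
})
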