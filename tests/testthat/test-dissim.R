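ct <- cell_type_set(c("A", "B", "C"))

mk <- function(id, edges) {
  # edges: named numeric vector like c("A,B" = 3)
  w <- matrix(0, 3, 3, dimnames = list(ct, ct))
  for (k in names(edges)) {
    ij <- strsplit(k, ",")[[1]]
    w[ij[1], ij[2]] <- edges[[k]]
  }
  build_layer(id, w, ct)
}

test_that("layer dissimilarity matches hand-evaluated cases", {
  a <- mk("a", c("A,B" = 1))
  expect_identical(layer_dissimilarity(a, a), 0)
  # direction matters: reversed edge is a full mismatch
  expect_identical(layer_dissimilarity(a, mk("r", c("B,A" = 1))), 1)
  # single shared edge with different weights: |3-1|/(3+1)
  expect_equal(layer_dissimilarity(mk("x", c("A,B" = 3)),
                                   mk("y", c("A,B" = 1))), 0.5)
  # one matched edge (score 0) plus one unmatched (score 1), union of 2
  expect_equal(layer_dissimilarity(mk("x", c("A,B" = 2, "A,C" = 2)),
                                   mk("y", c("A,B" = 2))), 0.5)
  # mismatched cell-type sets refused
  other <- build_layer("z", matrix(1, 2, 2), cell_type_set(c("A", "B")))
  expect_error(layer_dissimilarity(a, other), "different cell-type sets")
})

test_that("dissimilarity agrees with the brute-force formula on random pairs", {
  set.seed(42)
  cts <- cell_type_set(paste0("T", 1:5))
  for (i in 1:120) {
    a <- rand_layer("a", cts, density = runif(1, 0.15, 0.7))
    b <- rand_layer("b", cts, density = runif(1, 0.15, 0.7))
    d <- layer_dissimilarity(a, b)
    expect_lt(abs(d - brute_dissim(a, b)), 1e-12)
    expect_gte(d, 0)
    expect_lte(d, 1)
    expect_identical(layer_dissimilarity(b, a), d)   # symmetry
    # common rescaling of both layers leaves d unchanged
    a2 <- a; a2$weights <- a2$weights * 7.3
    b2 <- b; b2$weights <- b2$weights * 7.3
    expect_equal(layer_dissimilarity(a2, b2), d, tolerance = 1e-12)
  }
})

test_that("binarize is idempotent and reduces d to the Jaccard distance", {
  set.seed(7)
  cts <- cell_type_set(paste0("T", 1:4))
  lay <- rand_layer("x", cts)
  expect_identical(binarize(binarize(lay)), binarize(lay))
  expect_true(all(binarize(lay)$weights %in% c(0, 1)))
  expect_identical(binarize(lay)$pair_id, lay$pair_id)
  for (i in 1:120) {
    a <- rand_layer("a", cts, density = runif(1, 0.2, 0.8))
    b <- rand_layer("b", cts, density = runif(1, 0.2, 0.8))
    expect_equal(layer_dissimilarity(binarize(a), binarize(b)),
                 jaccard_dist(edge_set(a), edge_set(b)),
                 tolerance = 1e-12)
  }
})

test_that("the pairwise matrix is symmetric, zero-diagonal and brute-force exact", {
  ctA <- cell_type_set(c("A", "B"))
  same <- matrix(c(0, 0, 2, 0), 2)
  net2 <- build_multiplex(list(build_layer("p", same, ctA),
                               build_layer("q", same, ctA)), ctA)
  expect_equal(pairwise_dissimilarity(net2)$values,
               matrix(0, 2, 2, dimnames = list(c("p", "q"), c("p", "q"))))

  # three pairwise edge-disjoint layers: all off-diagonal d = 1
  dis <- build_multiplex(list(mk("1", c("A,B" = 1)),
                              mk("2", c("B,C" = 2)),
                              mk("3", c("C,A" = 3))), ct)
  v <- pairwise_dissimilarity(dis)$values
  expect_identical(v[upper.tri(v)], rep(1, 3))

  set.seed(13)
  cts <- cell_type_set(paste0("T", 1:5))
  net <- build_multiplex(lapply(1:5, function(i)
    rand_layer(paste0("p", i), cts)), cts)
  dm <- pairwise_dissimilarity(net)
  expect_identical(dm$values, t(dm$values))          # mirrored exactly
  expect_identical(diag(dm$values), setNames(rep(0, 5), dm$pair_ids))
  for (i in 1:4) for (j in (i + 1):5)
    expect_lt(abs(dm$values[i, j] -
                  brute_dissim(net$layers[[i]], net$layers[[j]])), 1e-12)

  one <- build_multiplex(net$layers[1], cts)
  expect_error(pairwise_dissimilarity(one), "at least 2")
})

test_that("dissimilarity matrices and layers round-trip through text files", {
  set.seed(99)
  cts <- cell_type_set(paste0("T", 1:4))
  net <- build_multiplex(lapply(1:4, function(i)
    rand_layer(paste0("p", i), cts)), cts)
  dm <- pairwise_dissimilarity(net)

  f <- withr::local_tempfile(fileext = ".csv")
  write_dissimilarity(dm, f)
  expect_identical(read_dissimilarity(f)$values, dm$values)

  g <- withr::local_tempfile(fileext = ".csv")
  write_layer_csv(net$layers[[1]], g)
  expect_identical(read_layer_csv(g, "p1")$weights, net$layers[[1]]$weights)

  h <- withr::local_tempfile(fileext = ".tsv")
  write_long_tsv(net, h)
  back <- read_long_tsv(h)
  expect_identical(back$cell_types, cts)
  for (id in pair_ids(net))
    expect_identical(back$layers[[id]]$weights, net$layers[[id]]$weights)
})
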