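# Independent oracles and small fixture builders shared by the tests.
# These deliberately avoid the package's vectorized code paths.

# cell-by-cell evaluation of the layer dissimilarity: loop over every
# ordered cell-type pair, score |dw|/(sum w) where either weight is
# positive, divide by the union size
brute_dissim <- function(a, b) {
  wa <- a$weights
  wb <- b$weights
  n <- nrow(wa)
  s_sum <- 0
  union <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      x <- wa[i, j]
      y <- wb[i, j]
      if (x > 0 || y > 0) {
        union <- union + 1
        s_sum <- s_sum + abs(x - y) / (x + y)
      }
    }
  }
  s_sum / union
}

# naive O(L^3) UPGMA on a dissimilarity matrix: repeatedly join the
# closest pair of clusters, distances updated as size-weighted means;
# ties resolved on the lowest pair of current cluster indices
upgma_heights <- function(d) {
  d <- as.matrix(d)
  L <- nrow(d)
  active <- seq_len(L)
  members <- as.list(seq_len(L))
  heights <- numeric(0)
  dd <- d
  while (length(active) > 1) {
    best <- c(NA, NA)
    best_d <- Inf
    for (ii in seq_along(active)[-length(active)]) {
      for (jj in seq.int(ii + 1, length(active))) {
        val <- dd[active[ii], active[jj]]
        if (val < best_d - 1e-15) {
          best_d <- val
          best <- c(ii, jj)
        }
      }
    }
    a <- active[best[1]]
    b <- active[best[2]]
    heights <- c(heights, best_d)
    na <- length(members[[a]])
    nb <- length(members[[b]])
    for (o in active) {
      if (o == a || o == b) next
      dd[a, o] <- dd[o, a] <- (na * dd[a, o] + nb * dd[b, o]) / (na + nb)
    }
    members[[a]] <- c(members[[a]], members[[b]])
    active <- setdiff(active, b)
  }
  heights
}

# directed edge set of a layer as linear indices
edge_set <- function(layer) which(layer$weights > 0)

# classical Jaccard distance between two index sets
jaccard_dist <- function(e1, e2) {
  1 - length(intersect(e1, e2)) / length(union(e1, e2))
}

# random valid (non-empty) layer over the given cell types; uses the
# session RNG so callers control the seed
rand_layer <- function(id, cell_types, density = 0.4) {
  n <- length(cell_types)
  repeat {
    w <- matrix(0, n, n)
    on <- stats::runif(n * n) < density
    w[on] <- stats::rexp(sum(on)) + 0.05
    if (any(w > 0)) break
  }
  build_layer(id, w, cell_types)
}

# symmetric dissimilarity-like matrix with zero diagonal, entries in (0,1)
rand_dissim_matrix <- function(L) {
  m <- matrix(0, L, L)
  vals <- stats::runif(L * (L - 1) / 2, 0.05, 0.95)
  m[lower.tri(m)] <- vals
  m <- m + t(m)
  dimnames(m) <- list(paste0("p", seq_len(L)), paste0("p", seq_len(L)))
  m
}

# planted two-archetype noiseless fixture: two disjoint single-block
# archetypes, unit weights, members identical within archetype
planted_noiseless <- function(members = 6, seed = 101) {
  arch1 <- matrix(0, 4, 4); arch1[1, 2:4] <- 1          # CT1 sends to all
  arch2 <- matrix(0, 4, 4); arch2[2:4, 1] <- 1          # all send to CT1
  spec <- archetype_spec(4, list(arch1, arch2), members,
                         weight_sigma = 0, edge_flip_prob = 0, seed = seed)
  generate_network(spec)
}
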