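# Synthetic multiplex communication networks with planted structure.
# Each archetype is a binary communication pattern over the cell types;
# members of an archetype start from that pattern, each cell is flipped
# independently with a small probability (present->absent and
# absent->present at the same rate, keeping expected density stable), and
# present edges get positive lognormal weights, mimicking the positive,
# right-skewed mean-expression scores produced by upstream tools.

#' Specify a planted-archetype synthetic network
#'
#' @param n_celltypes Number of cell types N (labels "CT1".."CTN").
#' @param archetypes List of distinct binary N x N matrices, each with at
#'   least one edge.
#' @param members_per_archetype Number of member layers per archetype.
#' @param weight_mu,weight_sigma Meanlog / sdlog of the lognormal edge
#'   weights (defaults 0 and 0.5; \code{weight_sigma = 0} gives unit
#'   weights).
#' @param edge_flip_prob Probability, in \code{[0, 0.5)}, that any given
#'   cell of a member's adjacency is flipped relative to its archetype.
#' @param seed Integer seed; generation is fully deterministic given the
#'   spec.
#' @return Object of class \code{"ccc_archetype_spec"}.
#' @export
archetype_spec <- function(n_celltypes, archetypes, members_per_archetype,
                           weight_mu = 0, weight_sigma = 0.5,
                           edge_flip_prob = 0, seed = 1L) {
  if (!is.numeric(n_celltypes) || n_celltypes < 2)
    stop("n_celltypes must be >= 2", call. = FALSE)
  n <- as.integer(n_celltypes)
  if (!is.list(archetypes) || length(archetypes) == 0)
    stop("need at least one archetype", call. = FALSE)
  for (a in archetypes) {
    if (!is.matrix(a) || any(dim(a) != n) || any(!a %in% c(0, 1)))
      stop("each archetype must be a binary N x N matrix", call. = FALSE)
    if (all(a == 0))
      stop("archetypes must have at least one edge", call. = FALSE)
  }
  keys <- vapply(archetypes, function(a) paste(a, collapse = ""), character(1))
  if (anyDuplicated(keys))
    stop("archetypes must be pairwise distinct", call. = FALSE)
  if (members_per_archetype < 1)
    stop("members_per_archetype must be >= 1", call. = FALSE)
  if (edge_flip_prob < 0 || edge_flip_prob >= 0.5)
    stop("edge_flip_prob must lie in [0, 0.5)", call. = FALSE)
  if (weight_sigma < 0)
    stop("weight_sigma must be >= 0", call. = FALSE)
  structure(list(n_celltypes = n,
                 archetypes = archetypes,
                 members_per_archetype = as.integer(members_per_archetype),
                 weight_mu = weight_mu, weight_sigma = weight_sigma,
                 edge_flip_prob = edge_flip_prob,
                 seed = as.integer(seed)),
            class = "ccc_archetype_spec")
}

#' Draw random distinct binary archetypes
#'
#' Helper for building an [archetype_spec()]: each archetype gets
#' \code{n_edges} directed edges placed uniformly at random; draws are
#' rejected until all archetypes share at most half of their edges with any
#' other, so the planted patterns are genuinely distinct.
#'
#' @param n_celltypes Number of cell types.
#' @param k Number of archetypes.
#' @param n_edges Edges per archetype (default: ~30\% of the N^2 cells).
#' @param seed Integer seed.
#' @return List of \code{k} binary matrices.
#' @export
random_archetypes <- function(n_celltypes, k, n_edges = NULL, seed = 1L) {
  n <- as.integer(n_celltypes)
  if (is.null(n_edges)) n_edges <- max(3L, round(0.3 * n * n))
  if (n_edges > n * n) stop("n_edges exceeds the number of cells", call. = FALSE)
  with_seed(as.integer(seed), {
    out <- list()
    guard <- 0L
    while (length(out) < k) {
      guard <- guard + 1L
      if (guard > 1000L)
        stop("could not draw sufficiently distinct archetypes", call. = FALSE)
      a <- matrix(0, n, n)
      a[sample.int(n * n, n_edges)] <- 1
      overlap_ok <- all(vapply(out, function(b)
        sum(a * b) <= n_edges / 2, logical(1)))
      if (overlap_ok) out[[length(out) + 1L]] <- a
    }
    out
  })
}

#' Generate a synthetic multiplex network with planted archetypes
#'
#' For each archetype, \code{members_per_archetype} layers are produced:
#' the archetype adjacency is copied, every cell is flipped independently
#' with probability \code{edge_flip_prob}, and each present edge receives a
#' weight drawn from the lognormal law. A member that ends up with no edge
#' at all is redrawn (the generator never emits empty layers). Output is
#' bit-identical for a fixed spec.
#'
#' @param spec An [archetype_spec()].
#' @return List with \code{network} (a [build_multiplex()] object; pair ids
#'   \code{"arch<k>:m<j>"}) and \code{truth} (named integer vector of
#'   planted archetype labels).
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "ccc_archetype_spec"))
  n <- spec$n_celltypes
  cell_types <- cell_type_set(paste0("CT", seq_len(n)))
  with_seed(spec$seed, {
    layers <- list()
    truth <- integer(0)
    for (k in seq_along(spec$archetypes)) {
      arch <- spec$archetypes[[k]]
      for (j in seq_len(spec$members_per_archetype)) {
        for (attempt in seq_len(100L)) {
          adj <- arch
          flip <- matrix(stats::runif(n * n) < spec$edge_flip_prob, n, n)
          adj[flip] <- 1 - adj[flip]
          if (any(adj == 1)) break
        }
        if (all(adj == 0)) adj <- arch  # pathological density; keep the planted pattern
        w <- matrix(0, n, n)
        present <- adj == 1
        w[present] <- stats::rlnorm(sum(present),
                                    meanlog = spec$weight_mu,
                                    sdlog = spec$weight_sigma)
        id <- sprintf("arch%d:m%d", k, j)
        layers[[length(layers) + 1L]] <- build_layer(id, w, cell_types)
        truth[id] <- k
      }
    }
    list(network = build_multiplex(layers, cell_types), truth = truth)
  })
}

#' Rewire a fraction of edges of selected layers
#'
#' Drives the differential-comparison tests: in each named layer, a
#' \code{rewire_frac} fraction of its edges (rounded) is moved, weights
#' intact, to cells chosen uniformly among the cells that were empty in the
#' original layer. All other layers are copied verbatim. At
#' \code{rewire_frac = 1} a layer's edge set becomes disjoint from the
#' original (dissimilarity 1); at 0 the network is returned unchanged.
#'
#' @param net A [build_multiplex()] network.
#' @param pair_ids Ids of the layers to perturb.
#' @param rewire_frac Fraction of edges to move, in \code{[0, 1]}.
#' @param seed Integer seed.
#' @return A perturbed copy of the network.
#' @export
perturb_network <- function(net, pair_ids, rewire_frac, seed = 1L) {
  stopifnot(inherits(net, "ccc_network"))
  unknown <- setdiff(pair_ids, names(net$layers))
  if (length(unknown) > 0)
    stop(sprintf("unknown pair_id(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  if (rewire_frac < 0 || rewire_frac > 1)
    stop("rewire_frac must lie in [0, 1]", call. = FALSE)
  if (rewire_frac == 0) return(net)
  with_seed(as.integer(seed), {
    for (id in pair_ids) {
      w <- net$layers[[id]]$weights
      present <- which(w > 0)
      absent <- which(w == 0)
      n_move <- min(round(rewire_frac * length(present)), length(absent))
      if (n_move == 0) next
      from <- if (length(present) == 1) present else sample(present, n_move)
      to <- if (length(absent) == 1) absent else sample(absent, n_move)
      w[to] <- w[from]
      w[from] <- 0
      net$layers[[id]]$weights <- w
    }
    net
  })
}
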