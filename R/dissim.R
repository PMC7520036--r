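#' Dissimilarity between two layers
#'
#' The measure is a weighted, directed modification of the Jaccard distance
#' between the edge sets of the two layers. Over the union of edges
#' E_alpha, E_beta (directed cell-type pairs, self-edges included, with a
#' positive weight in at least one layer), each edge contributes the
#' relative weight difference
#' \deqn{s_{ij} = |w^\alpha_{ij} - w^\beta_{ij}| / (w^\alpha_{ij} + w^\beta_{ij})}
#' and the dissimilarity is the mean contribution
#' \deqn{d_{\alpha\beta} = \sum_{ij} s_{ij} / |E_\alpha \cup E_\beta|.}
#' Cells where both weights are zero contribute nothing. An edge present in
#' only one layer scores 1; an edge with equal weights scores 0. Hence
#' d = 0 iff the two weight matrices are identical on the union, d = 1 iff
#' the edge sets are disjoint, and on binarized layers d reduces to the
#' classical Jaccard distance of directed edge sets. d is invariant under
#' rescaling both layers by the same positive constant.
#'
#' @param alpha,beta Layers built against the same cell-type set.
#' @return A single number in \code{[0, 1]}.
#' @examples
#' ct <- cell_type_set(c("A", "B"))
#' a <- build_layer("a", matrix(c(0, 0, 3, 0), 2), ct)
#' b <- build_layer("b", matrix(c(0, 0, 1, 0), 2), ct)
#' layer_dissimilarity(a, b)  # |3-1|/(3+1) / 1 = 0.5
#' @export
layer_dissimilarity <- function(alpha, beta) {
  stopifnot(inherits(alpha, "ccc_layer"), inherits(beta, "ccc_layer"))
  if (!identical(rownames(alpha$weights), rownames(beta$weights)))
    stop("layers are indexed against different cell-type sets", call. = FALSE)
  a <- alpha$weights
  b <- beta$weights
  u <- (a > 0) | (b > 0)
  sum(abs(a[u] - b[u]) / (a[u] + b[u])) / sum(u)
}

#' All pairwise layer dissimilarities of a network
#'
#' Each unordered pair is computed once and mirrored, so the result is
#' symmetric exactly, with a zero diagonal.
#'
#' @param net A [build_multiplex()] network with at least two layers.
#' @return Object of class \code{"ccc_dissim"}: list with \code{values}
#'   (symmetric L x L matrix, pair ids as dimnames) and \code{pair_ids}.
#' @export
pairwise_dissimilarity <- function(net) {
  stopifnot(inherits(net, "ccc_network"))
  L <- length(net$layers)
  if (L < 2)
    stop("pairwise dissimilarity needs at least 2 layers", call. = FALSE)
  ids <- pair_ids(net)
  d <- matrix(0, L, L, dimnames = list(ids, ids))
  for (i in seq_len(L - 1L))
    for (j in seq.int(i + 1L, L)) {
      d[i, j] <- d[j, i] <- layer_dissimilarity(net$layers[[i]], net$layers[[j]])
    }
  structure(list(values = d, pair_ids = ids), class = "ccc_dissim")
}

#' @export
print.ccc_dissim <- function(x, ...) {
  cat(sprintf("<layer dissimilarity matrix> %d x %d, range [%.3g, %.3g]\n",
              nrow(x$values), ncol(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
as.dist.ccc_dissim <- function(m, diag = FALSE, upper = FALSE)
  stats::as.dist(m$values, diag = diag, upper = upper)

#' Binarize a layer on edge presence/absence
#'
#' Weight becomes 1 wherever the original weight is positive, 0 elsewhere.
#' Used by the pattern search, where only the shape of the communication
#' pattern matters, not its strength. Idempotent; pair id and direction
#' flag are preserved.
#'
#' @param layer A [build_layer()] object.
#' @return A layer with 0/1 weights.
#' @export
binarize <- function(layer) {
  stopifnot(inherits(layer, "ccc_layer"))
  layer$weights[] <- as.numeric(layer$weights > 0)
  layer
}

# shared validity check for a dissimilarity matrix in raw matrix form
validate_dissim_matrix <- function(values, tol = 1e-12) {
  if (!is.matrix(values) || nrow(values) != ncol(values))
    stop("dissimilarity matrix must be square", call. = FALSE)
  if (any(!is.finite(values)))
    stop("dissimilarity matrix must be finite", call. = FALSE)
  if (any(values < -tol) || any(values > 1 + tol))
    stop("dissimilarities must lie in [0, 1]", call. = FALSE)
  if (!isTRUE(all.equal(values, t(values), tolerance = tol, check.attributes = FALSE)))
    stop("dissimilarity matrix must be symmetric", call. = FALSE)
  if (any(abs(diag(values)) > tol))
    stop("dissimilarity matrix must have a zero diagonal", call. = FALSE)
  invisible(values)
}
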