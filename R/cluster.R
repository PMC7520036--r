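#' Hierarchical clustering of the layer dissimilarity matrix
#'
#' Average-linkage (UPGMA) agglomeration by default, via
#' \code{\link[stats]{hclust}} on the precomputed dissimilarities.
#'
#' @param dm A [pairwise_dissimilarity()] object, or a square symmetric
#'   matrix of dissimilarities in \code{[0, 1]}.
#' @param method Agglomeration method passed to \code{hclust}.
#' @return An \code{hclust} tree with pair ids as labels.
#' @export
hierarchical_linkage <- function(dm, method = "average") {
  values <- if (inherits(dm, "ccc_dissim")) dm$values else dm
  validate_dissim_matrix(values)
  if (nrow(values) < 2)
    stop("need at least 2 layers to cluster", call. = FALSE)
  stats::hclust(stats::as.dist(values), method = method)
}

#' Cluster layers with the hybrid dynamic tree cut
#'
#' Cuts the average-linkage tree with the Dynamic Hybrid procedure
#' ([cutree_hybrid()]): clusters are tight, well-separated branches with at
#' least \code{min_cluster_size} members; layers that fit no cluster keep
#' label 0 and are excluded from average patterns.
#'
#' @param linkage An \code{hclust} tree from [hierarchical_linkage()].
#' @param dm The dissimilarity matrix the tree was built from.
#' @param deep_split Split sensitivity, integer 0..4 (default 0, the
#'   coarsest).
#' @param min_cluster_size Minimum cluster size (default 6).
#' @param ... Further arguments passed to [cutree_hybrid()].
#' @return Object of class \code{"ccc_clusters"}: list with \code{labels}
#'   (named integer vector, 0 = unassigned), \code{n_clusters} and
#'   \code{linkage}.
#' @export
hybrid_tree_cut <- function(linkage, dm, deep_split = 0, min_cluster_size = 6,
                            ...) {
  values <- if (inherits(dm, "ccc_dissim")) dm$values else dm
  validate_dissim_matrix(values)
  lab <- cutree_hybrid(linkage, values, deep_split = deep_split,
                       min_cluster_size = min_cluster_size, ...)
  n_clusters <- attr(lab, "n_clusters")
  attr(lab, "n_clusters") <- NULL
  if (is.null(names(lab)) && !is.null(rownames(values)))
    names(lab) <- rownames(values)
  structure(list(labels = lab, n_clusters = n_clusters, linkage = linkage),
            class = "ccc_clusters")
}

#' @export
print.ccc_clusters <- function(x, ...) {
  cat(sprintf("<layer clustering> %d cluster(s), %d of %d layers assigned\n",
              x$n_clusters, sum(x$labels > 0), length(x$labels)))
  if (x$n_clusters > 0)
    print(table(cluster = x$labels[x$labels > 0]))
  invisible(x)
}

#' Average communication pattern of one cluster
#'
#' The representative pattern of a cluster is the arithmetic mean of its
#' members' weight matrices together with the mean per-node send/receive
#' balance. Because the balance is linear in the weights, the mean balance
#' equals the balance of the mean matrix.
#'
#' @param net The clustered [build_multiplex()] network.
#' @param assignment A [hybrid_tree_cut()] result for that network.
#' @param cluster_label Label (>= 1) of the cluster to summarise.
#' @return Object of class \code{"ccc_pattern"}: list with
#'   \code{cluster_label}, \code{members} (pair ids), \code{mean_weights}
#'   and \code{mean_delta}.
#' @export
average_pattern <- function(net, assignment, cluster_label) {
  stopifnot(inherits(net, "ccc_network"), inherits(assignment, "ccc_clusters"))
  if (!is.numeric(cluster_label) || length(cluster_label) != 1 ||
      cluster_label < 1)
    stop("cluster_label must be a single label >= 1", call. = FALSE)
  members <- names(assignment$labels)[assignment$labels == cluster_label]
  if (length(members) == 0)
    stop(sprintf("no cluster with label %s", cluster_label), call. = FALSE)
  missing <- setdiff(members, pair_ids(net))
  if (length(missing) > 0)
    stop("assignment refers to layers absent from the network", call. = FALSE)
  mats <- lapply(net$layers[members], `[[`, "weights")
  mean_w <- Reduce(`+`, mats) / length(mats)
  structure(list(cluster_label = as.integer(cluster_label),
                 members = members,
                 mean_weights = mean_w,
                 mean_delta = rowSums(mean_w) - colSums(mean_w)),
            class = "ccc_pattern")
}

#' @export
print.ccc_pattern <- function(x, ...) {
  cat(sprintf("<average pattern of cluster %d> %d member layer(s)\n",
              x$cluster_label, length(x$members)))
  invisible(x)
}

#' Two-dimensional embedding of the layers
#'
#' Embeds the layers from their precomputed dissimilarity matrix, by UMAP
#' when the \pkg{uwot} package is installed, otherwise by classical metric
#' MDS (\code{\link[stats]{cmdscale}}). Deterministic for a fixed seed.
#'
#' @param dm A [pairwise_dissimilarity()] object or square dissimilarity
#'   matrix with at least 4 layers.
#' @param seed Integer seed controlling the (UMAP) embedding.
#' @param method \code{"auto"} (UMAP when available), \code{"umap"} or
#'   \code{"mds"}.
#' @param n_neighbors UMAP neighborhood size; the default, \code{min(5,
#'   L - 1)}, keeps neighborhoods no larger than the smallest cluster the
#'   tree cut reports (one less than the default minimum cluster size of
#'   6), so distinct communication patterns are not bridged in the
#'   embedding.
#' @return An L x 2 numeric matrix of coordinates, pair ids as row names,
#'   with attribute \code{"method"} recording which embedding was used.
#' @export
embed_layers <- function(dm, seed = 1L, method = c("auto", "umap", "mds"),
                         n_neighbors = NULL) {
  method <- match.arg(method)
  values <- if (inherits(dm, "ccc_dissim")) dm$values else dm
  validate_dissim_matrix(values)
  L <- nrow(values)
  if (L < 4)
    stop("embedding needs at least 4 layers", call. = FALSE)
  if (method == "auto")
    method <- if (requireNamespace("uwot", quietly = TRUE)) "umap" else "mds"
  if (method == "umap" && !requireNamespace("uwot", quietly = TRUE))
    stop("the uwot package is required for method = 'umap'", call. = FALSE)
  if (is.null(n_neighbors)) n_neighbors <- max(2L, min(5L, L - 1L))
  if (method == "umap") {
    coords <- with_seed(as.integer(seed), {
      suppressWarnings(uwot::umap(stats::as.dist(values),
                                  n_neighbors = min(n_neighbors, L - 1L),
                                  n_threads = 1, n_sgd_threads = 1,
                                  batch = TRUE))
    })
  } else {
    coords <- stats::cmdscale(stats::as.dist(values), k = 2)
    if (ncol(coords) < 2)  # degenerate (e.g. all points coincide on one axis)
      coords <- cbind(coords, matrix(0, nrow(coords), 2 - ncol(coords)))
  }
  coords <- unname(coords)[, 1:2, drop = FALSE]
  dimnames(coords) <- list(rownames(values), c("dim1", "dim2"))
  attr(coords, "method") <- method
  coords
}

# run an expression under a temporary RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
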