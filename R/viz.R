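# Figures in the method's visual vocabulary: communication graphs with a
# fixed circular cell-type layout and diverging red/blue node colors by the
# send/receive balance, a dissimilarity heatmap, and the 2-D layer
# embedding. Rendering never mutates its inputs; all figures are
# reproducible (no randomized layouts).

ccc_device <- function(path, width, height) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         svg = grDevices::svg(path, width = width, height = height),
         png = grDevices::png(path, width = width * 96, height = height * 96,
                              res = 96),
         pdf = grDevices::pdf(path, width = width, height = height),
         stop(sprintf("unsupported figure format '.%s' (use svg, png or pdf)",
                      ext), call. = FALSE))
}

# diverging blue-white-red color for delta values, symmetric about 0 so
# that sign (send vs. receive) maps to hue and magnitude to saturation
delta_colors <- function(delta, delta_max = NULL) {
  if (is.null(delta_max)) delta_max <- max(abs(delta), 1e-12)
  pal <- grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(201)
  idx <- round((pmax(pmin(delta / delta_max, 1), -1) + 1) * 100) + 1
  pal[idx]
}

#' Plot one layer (or cluster average pattern) as a communication graph
#'
#' Nodes are the cell types, on a fixed circle in cell-type order so that
#' patterns are comparable by eye across figures; arrows run sender to
#' receiver, edge width is linear in weight, self-edges are drawn as loops.
#' Node fill encodes the send/receive balance: red for net senders
#' (positive delta), blue for net receivers.
#'
#' @param x A [build_layer()] layer or [average_pattern()] object.
#' @param path Output file; format from the extension (svg, png or pdf).
#' @param delta_max Color-scale bound; defaults to the maximum absolute
#'   balance in this figure (pass a common value to make a set of figures
#'   color-comparable).
#' @param max_edge_width Width of the heaviest edge, in lines.
#' @return The path, invisibly.
#' @export
plot_layer <- function(x, path, delta_max = NULL, max_edge_width = 6) {
  if (inherits(x, "ccc_pattern")) {
    w <- x$mean_weights
    main <- sprintf("cluster %d average (%d layers)",
                    x$cluster_label, length(x$members))
  } else {
    stopifnot(inherits(x, "ccc_layer"))
    w <- x$weights
    main <- x$pair_id
  }
  delta <- rowSums(w) - colSums(w)
  g <- igraph::graph_from_adjacency_matrix(w, mode = "directed",
                                           weighted = TRUE, diag = TRUE)
  n <- nrow(w)
  layout <- cbind(cos(2 * pi * (seq_len(n) - 1) / n),
                  sin(2 * pi * (seq_len(n) - 1) / n))
  ew <- igraph::E(g)$weight
  ccc_device(path, 6, 6)
  on.exit(grDevices::dev.off())
  igraph::plot.igraph(
    g, layout = layout, main = main,
    vertex.color = delta_colors(delta, delta_max),
    vertex.size = 30, vertex.label.color = "black",
    edge.width = if (length(ew)) max_edge_width * ew / max(ew) else 1,
    edge.arrow.size = 0.6, edge.color = "grey40", edge.curved = 0.15)
  invisible(path)
}

#' Heatmap of the layer dissimilarity matrix
#'
#' Rows and columns are ordered by the average-linkage dendrogram (computed
#' from the matrix itself, or taken from a cluster assignment when given,
#' whose labels annotate the rows).
#'
#' @param dm A [pairwise_dissimilarity()] object.
#' @param path Output file (svg, png or pdf).
#' @param assignment Optional [hybrid_tree_cut()] result; supplies the
#'   dendrogram and a cluster annotation.
#' @return The path, invisibly.
#' @export
plot_heatmap <- function(dm, path, assignment = NULL) {
  stopifnot(inherits(dm, "ccc_dissim"))
  tree <- if (!is.null(assignment)) {
    stopifnot(inherits(assignment, "ccc_clusters"))
    assignment$linkage
  } else {
    hierarchical_linkage(dm)
  }
  ann <- NA
  if (!is.null(assignment)) {
    ann <- data.frame(cluster = factor(assignment$labels),
                      row.names = names(assignment$labels))
  }
  ccc_device(path, 7, 6.5)
  on.exit(grDevices::dev.off())
  pheatmap::pheatmap(dm$values,
                     cluster_rows = stats::as.hclust(tree),
                     cluster_cols = stats::as.hclust(tree),
                     annotation_row = ann,
                     breaks = seq(0, 1, length.out = 101),
                     main = "layer dissimilarity")
  invisible(path)
}

#' Scatter plot of the 2-D layer embedding
#'
#' @param coords An [embed_layers()] result.
#' @param path Output file (svg, png or pdf).
#' @param assignment Optional [hybrid_tree_cut()] result used to color the
#'   points by cluster (0 = unassigned, grey).
#' @return The path, invisibly.
#' @export
plot_embedding <- function(coords, path, assignment = NULL) {
  stopifnot(is.matrix(coords), ncol(coords) == 2)
  col <- "grey30"
  if (!is.null(assignment)) {
    lab <- assignment$labels[rownames(coords)]
    pal <- c("grey70", grDevices::hcl.colors(max(lab, 1), "Dark 3"))
    col <- pal[lab + 1]
  }
  ccc_device(path, 6, 6)
  on.exit(grDevices::dev.off())
  graphics::plot(coords, col = col, pch = 19,
                 xlab = "dim 1", ylab = "dim 2",
                 main = sprintf("layer embedding (%s)",
                                attr(coords, "method") %||% "precomputed"))
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
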