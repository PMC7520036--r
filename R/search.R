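#' Define a binary communication pattern to search for
#'
#' The query is a binary adjacency matrix over the network's cell types:
#' 1 marks a required directed edge (sender row, receiver column), 0 marks
#' absence. At least one edge is required.
#'
#' @param adjacency Square 0/1 matrix over \code{cell_types}.
#' @param cell_types Ordered cell-type labels the matrix is indexed by.
#' @return Object of class \code{"ccc_query"}.
#' @export
pattern_query <- function(adjacency, cell_types) {
  cell_types <- cell_type_set(cell_types)
  if (!is.matrix(adjacency) || !is.numeric(adjacency) ||
      nrow(adjacency) != ncol(adjacency))
    stop("the query must be a square numeric matrix", call. = FALSE)
  if (nrow(adjacency) != length(cell_types))
    stop("query dimension does not match the cell-type set", call. = FALSE)
  if (any(!adjacency %in% c(0, 1)))
    stop("query entries must be 0 or 1", call. = FALSE)
  if (all(adjacency == 0))
    stop("the query pattern is empty (no edge required)", call. = FALSE)
  dimnames(adjacency) <- list(cell_types, cell_types)
  structure(list(adjacency = adjacency, cell_types = cell_types),
            class = "ccc_query")
}

#' Rank interacting pairs by similarity to a communication pattern
#'
#' Every layer is binarized on edge presence and compared to the query with
#' the modified Jaccard dissimilarity, which on binary layers equals the
#' classical Jaccard distance of the two directed edge sets. The result is
#' sorted by increasing dissimilarity, so exact matches come first; ties are
#' broken by pair id, lexicographically, for determinism. Original weights
#' never influence the ranking.
#'
#' @param net A [build_multiplex()] network.
#' @param query A [pattern_query()] over the same cell types.
#' @return Object of class \code{"ccc_ranking"}: a data frame with columns
#'   \code{rank}, \code{pair_id}, \code{dissimilarity}, attribute
#'   \code{"order"} set to \code{"ascending"}.
#' @export
search_pattern <- function(net, query) {
  stopifnot(inherits(net, "ccc_network"), inherits(query, "ccc_query"))
  if (!identical(query$cell_types, net$cell_types))
    stop("query and network use different cell-type sets", call. = FALSE)
  qlayer <- build_layer("query", query$adjacency, net$cell_types)
  d <- vapply(net$layers,
              function(lay) layer_dissimilarity(binarize(lay), qlayer),
              double(1))
  ranking_table(names(d), unname(d), decreasing = FALSE)
}

# shared constructor for ranked pair lists (search: ascending; comparison:
# descending); ties broken lexicographically on pair_id
ranking_table <- function(ids, d, decreasing) {
  stopifnot(all(d >= 0 & d <= 1 + 1e-12))
  key <- if (decreasing) -d else d
  ord <- order(key, ids, method = "radix")
  out <- data.frame(rank = seq_along(ids),
                    pair_id = ids[ord],
                    dissimilarity = d[ord],
                    stringsAsFactors = FALSE,
                    row.names = NULL)
  class(out) <- c("ccc_ranking", "data.frame")
  attr(out, "order") <- if (decreasing) "descending" else "ascending"
  out
}

#' @export
print.ccc_ranking <- function(x, ...) {
  cat(sprintf("<ranked pair list> %d pairs, %s dissimilarity\n",
              nrow(x), attr(x, "order")))
  print.data.frame(utils::head(x, 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}
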