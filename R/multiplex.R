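#' Validate an ordered set of cell-type labels
#'
#' Cell types are the nodes shared by every layer of a multiplex
#' communication network. Their order is fixed for the lifetime of a
#' network: every weight matrix is indexed against it (rows = sender,
#' columns = receiver).
#'
#' @param names Character vector of unique, non-empty labels (length >= 2).
#' @return The validated character vector, invisibly classed as used
#'   throughout the package (a plain character vector).
#' @export
cell_type_set <- function(names) {
  if (!is.character(names) || length(names) < 2)
    stop("cell types must be a character vector of length >= 2", call. = FALSE)
  names <- trimws(names)
  if (anyNA(names) || any(!nzchar(names)))
    stop("cell-type labels must be non-empty", call. = FALSE)
  if (anyDuplicated(names))
    stop("cell-type labels must be unique", call. = FALSE)
  names
}

#' Build one layer of a multiplex communication network
#'
#' A layer is the directed weighted graph of a single interacting pair
#' (typically ligand:receptor). Entry \code{weights[i, j]} is the weight of
#' the directed edge from cell type \code{i} (sender, expressing the ligand
#' or partner P1) to cell type \code{j} (receiver, expressing the receptor
#' or partner P2). Weights are the upstream tool's scores (e.g. significant
#' mean expression); an edge exists iff its weight is strictly positive.
#' Self-edges (autocrine signalling) are permitted.
#'
#' @param pair_id Label of the interacting pair, e.g. \code{"Lefty1:Tdgf1"}.
#' @param weights Square numeric matrix, dimension \code{N x N} matching
#'   \code{cell_types}, all entries finite and non-negative, at least one
#'   positive (all-zero layers are rejected: they carry no communication and
#'   would make the dissimilarity denominator zero).
#' @param cell_types Ordered cell-type labels (see [cell_type_set()]).
#' @param directional \code{TRUE} for ligand->receptor pairs, \code{FALSE}
#'   for unordered partners P1/P2 (e.g. adhesion molecules), where the edge
#'   still runs P1-expresser -> P2-expresser by convention.
#' @return An object of class \code{"ccc_layer"}: a list with elements
#'   \code{pair_id}, \code{weights} (with cell-type dimnames) and
#'   \code{directional}.
#' @examples
#' ct <- cell_type_set(c("A", "B"))
#' lay <- build_layer("L:R", matrix(c(0, 0, 3, 0), 2), ct)
#' node_delta(lay)
#' @export
build_layer <- function(pair_id, weights, cell_types, directional = TRUE) {
  cell_types <- cell_type_set(cell_types)
  if (!is.character(pair_id) || length(pair_id) != 1 || !nzchar(trimws(pair_id)))
    stop("pair_id must be a single non-empty string", call. = FALSE)
  if (!is.matrix(weights) || !is.numeric(weights))
    stop("weights must be a numeric matrix", call. = FALSE)
  n <- length(cell_types)
  if (nrow(weights) != ncol(weights))
    stop("weight matrix must be square", call. = FALSE)
  if (nrow(weights) != n)
    stop(sprintf("weight matrix is %dx%d but there are %d cell types",
                 nrow(weights), ncol(weights), n), call. = FALSE)
  if (any(!is.finite(weights)))
    stop("weights must be finite", call. = FALSE)
  if (any(weights < 0))
    stop("weights must be non-negative", call. = FALSE)
  if (all(weights == 0))
    stop(sprintf("layer '%s' is empty (all weights zero)", pair_id), call. = FALSE)
  if (!is.null(dimnames(weights))) {
    if (!identical(rownames(weights), cell_types) ||
        !identical(colnames(weights), cell_types))
      stop("weight matrix dimnames disagree with cell_types", call. = FALSE)
  }
  dimnames(weights) <- list(cell_types, cell_types)
  structure(list(pair_id = trimws(pair_id),
                 weights = weights,
                 directional = isTRUE(directional)),
            class = "ccc_layer")
}

#' @export
print.ccc_layer <- function(x, ...) {
  cat(sprintf("<layer '%s'> %d cell types, %d edge(s), %s\n",
              x$pair_id, nrow(x$weights), sum(x$weights > 0),
              if (x$directional) "ligand->receptor" else "P1->P2"))
  invisible(x)
}

#' Per-node send/receive balance of a layer
#'
#' For each cell type the balance Delta = weighted out-degree minus weighted
#' in-degree. Positive Delta marks a predominantly sending node (producing
#' the ligand; drawn red), negative a predominantly receiving node (blue).
#' Self-edges contribute equally to both degrees and so cancel; the Delta
#' values always sum to zero exactly.
#'
#' @param layer A [build_layer()] object.
#' @return Named numeric vector of Delta values, one per cell type, in the
#'   units of the layer weights.
#' @export
node_delta <- function(layer) {
  stopifnot(inherits(layer, "ccc_layer"))
  rowSums(layer$weights) - colSums(layer$weights)
}

#' Stack layers into a multiplex network
#'
#' All layers must be built against the same ordered cell-type set and carry
#' unique pair ids; input order is preserved.
#'
#' @param layers List of [build_layer()] objects (at least one).
#' @param cell_types Ordered cell-type labels shared by all layers.
#' @return Object of class \code{"ccc_network"}: list with \code{cell_types}
#'   and \code{layers} (named by pair id).
#' @export
build_multiplex <- function(layers, cell_types) {
  cell_types <- cell_type_set(cell_types)
  if (!is.list(layers) || length(layers) == 0)
    stop("a multiplex network needs at least one layer", call. = FALSE)
  ok <- vapply(layers, inherits, logical(1), what = "ccc_layer")
  if (!all(ok))
    stop("all elements of 'layers' must be ccc_layer objects", call. = FALSE)
  for (lay in layers)
    if (!identical(rownames(lay$weights), cell_types))
      stop(sprintf("layer '%s' is indexed against a different cell-type set",
                   lay$pair_id), call. = FALSE)
  ids <- vapply(layers, `[[`, character(1), "pair_id")
  if (anyDuplicated(ids))
    stop(sprintf("duplicate pair_id: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  names(layers) <- ids
  structure(list(cell_types = cell_types, layers = layers),
            class = "ccc_network")
}

#' @export
print.ccc_network <- function(x, ...) {
  cat(sprintf("<multiplex communication network> %d layers over %d cell types\n",
              length(x$layers), length(x$cell_types)))
  cat("cell types:", paste(x$cell_types, collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.ccc_network <- function(x) length(x$layers)

#' Pair ids of a network's layers, in layer order
#' @param net A [build_multiplex()] object.
#' @return Character vector.
#' @export
pair_ids <- function(net) {
  stopifnot(inherits(net, "ccc_network"))
  names(net$layers)
}
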