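# Plain-text I/O for layers, networks, dissimilarity matrices, cluster
# assignments and pattern queries. All numeric output uses %.17g so that
# decimal text round-trips bit-stably.

fmt_num <- function(x) sprintf("%.17g", x)

#' Write / read one layer as a CSV weight matrix
#'
#' N x N matrix with a header row and an index column of cell-type labels;
#' rows are senders, columns receivers.
#'
#' @param layer A [build_layer()] object.
#' @param path File path.
#' @rdname layer_csv
#' @export
write_layer_csv <- function(layer, path) {
  stopifnot(inherits(layer, "ccc_layer"))
  w <- layer$weights
  lines <- c(paste(c("", colnames(w)), collapse = ","),
             vapply(seq_len(nrow(w)), function(i)
               paste(c(rownames(w)[i], fmt_num(w[i, ])), collapse = ","),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @param pair_id Pair id to give the layer read from \code{path}.
#' @param directional Direction flag for the layer read from \code{path}.
#' @rdname layer_csv
#' @export
read_layer_csv <- function(path, pair_id, directional = TRUE) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  if (!identical(rownames(m), colnames(m)))
    stop(sprintf("'%s': row and column labels disagree", path), call. = FALSE)
  build_layer(pair_id, m, rownames(m), directional = directional)
}

#' Write / read a whole network in long (edge-list) format
#'
#' Tab-separated columns \code{pair_id}, \code{sender}, \code{receiver},
#' \code{weight}, \code{directional}; only edges with positive weight are
#' written. A comment header \code{# cell_types: ...} preserves the full
#' ordered cell-type set (including types with no edges). Readers accept
#' plain 4-column files without the comment, inferring cell types from the
#' data in order of appearance.
#'
#' @param net A [build_multiplex()] network.
#' @param path File path.
#' @rdname long_tsv
#' @export
write_long_tsv <- function(net, path) {
  stopifnot(inherits(net, "ccc_network"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# cell_types: ", paste(net$cell_types, collapse = ",")), con)
  writeLines("pair_id\tsender\treceiver\tweight\tdirectional", con)
  for (lay in net$layers) {
    idx <- which(lay$weights > 0, arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    writeLines(paste(lay$pair_id,
                     rownames(lay$weights)[idx[, 1]],
                     colnames(lay$weights)[idx[, 2]],
                     fmt_num(lay$weights[idx]),
                     lay$directional,
                     sep = "\t"), con)
  }
  invisible(path)
}

#' @param cell_types Optional explicit ordered cell-type set; otherwise the
#'   \code{# cell_types:} header is used, or, failing that, labels in order
#'   of appearance.
#' @rdname long_tsv
#' @export
read_long_tsv <- function(path, cell_types = NULL) {
  first <- readLines(path, n = 1)
  if (is.null(cell_types) && startsWith(first, "# cell_types:")) {
    cell_types <- trimws(strsplit(sub("^# cell_types:", "", first), ",")[[1]])
  }
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("pair_id", "sender", "receiver", "weight")
  if (!all(need %in% names(df)))
    stop(sprintf("'%s': expected columns %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  if (!"directional" %in% names(df)) df$directional <- TRUE
  if (is.null(cell_types))
    cell_types <- unique(c(rbind(df$sender, df$receiver)))
  cell_types <- cell_type_set(cell_types)
  bad <- setdiff(unique(c(df$sender, df$receiver)), cell_types)
  if (length(bad) > 0)
    stop(sprintf("'%s': unknown cell type(s): %s", path,
                 paste(bad, collapse = ", ")), call. = FALSE)
  layers <- lapply(split(df, factor(df$pair_id, levels = unique(df$pair_id))),
                   function(sub) {
                     w <- matrix(0, length(cell_types), length(cell_types),
                                 dimnames = list(cell_types, cell_types))
                     w[cbind(sub$sender, sub$receiver)] <- sub$weight
                     build_layer(sub$pair_id[1], w, cell_types,
                                 directional = all(as.logical(sub$directional)))
                   })
  build_multiplex(unname(layers), cell_types)
}

#' Write / read a dissimilarity matrix as CSV
#'
#' Square CSV with pair ids as header and index, full double precision.
#'
#' @param dm A [pairwise_dissimilarity()] object.
#' @param path File path.
#' @rdname dissim_csv
#' @export
write_dissimilarity <- function(dm, path) {
  stopifnot(inherits(dm, "ccc_dissim"))
  v <- dm$values
  lines <- c(paste(c("", dm$pair_ids), collapse = ","),
             vapply(seq_len(nrow(v)), function(i)
               paste(c(dm$pair_ids[i], fmt_num(v[i, ])), collapse = ","),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname dissim_csv
#' @export
read_dissimilarity <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  if (!identical(rownames(m), colnames(m)))
    stop(sprintf("'%s': row and column labels disagree", path), call. = FALSE)
  validate_dissim_matrix(m)
  structure(list(values = m, pair_ids = rownames(m)), class = "ccc_dissim")
}

#' Write a cluster assignment as TSV
#'
#' Two columns, \code{pair_id} and \code{cluster_label} (0 = unassigned),
#' in the input layer order.
#'
#' @param assignment A [hybrid_tree_cut()] result.
#' @param path File path.
#' @export
write_clusters <- function(assignment, path) {
  stopifnot(inherits(assignment, "ccc_clusters"))
  lines <- c("pair_id\tcluster_label",
             paste(names(assignment$labels), assignment$labels, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a pattern query from file
#'
#' Either a CSV binary adjacency matrix with cell-type header and index
#' (like [write_layer_csv()] output), or a two-column edge-list TSV with
#' columns \code{sender} and \code{receiver}; the edge-list form requires an
#' explicit \code{cell_types}.
#'
#' @param path File path.
#' @param cell_types Ordered cell-type set the query must be indexed by;
#'   optional for the matrix form (taken from the file), required for the
#'   edge-list form.
#' @return A [pattern_query()] object.
#' @export
read_pattern_query <- function(path, cell_types = NULL) {
  header <- readLines(path, n = 1)
  if (grepl("\t", header)) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("sender", "receiver") %in% names(df)))
      stop(sprintf("'%s': edge-list query needs columns sender, receiver", path),
           call. = FALSE)
    if (is.null(cell_types))
      stop("cell_types is required for an edge-list query", call. = FALSE)
    cell_types <- cell_type_set(cell_types)
    adj <- matrix(0, length(cell_types), length(cell_types),
                  dimnames = list(cell_types, cell_types))
    bad <- setdiff(unique(c(df$sender, df$receiver)), cell_types)
    if (length(bad) > 0)
      stop(sprintf("'%s': unknown cell type(s): %s", path,
                   paste(bad, collapse = ", ")), call. = FALSE)
    adj[cbind(df$sender, df$receiver)] <- 1
  } else {
    df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
    adj <- as.matrix(df)
    if (is.null(cell_types)) cell_types <- rownames(adj)
    if (!identical(rownames(adj), colnames(adj)))
      stop(sprintf("'%s': row and column labels disagree", path), call. = FALSE)
  }
  pattern_query(adj, cell_types)
}

#' Write a ranked pair list as TSV
#'
#' @param ranking A [search_pattern()] or comparison ranking.
#' @param path File path.
#' @export
write_ranking <- function(ranking, path) {
  stopifnot(inherits(ranking, "ccc_ranking"))
  df <- as.data.frame(ranking)
  df$dissimilarity <- fmt_num(df$dissimilarity)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
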