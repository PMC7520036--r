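# CellPhoneDB v2 result-table input. Two dialects:
#  * significant_means: one tab-separated table; metadata columns followed
#    by one column per ordered cell-type pair "A|B" holding the significant
#    mean expression, empty when not significant.
#  * means + pvalues: two parallel tables; the mean becomes the weight
#    where the p-value passes the threshold.

#' Read a CellPhoneDB-style significant-means table
#'
#' Parses the tab-separated v2 \code{significant_means} output: interaction
#' metadata columns (at least \code{interacting_pair}, \code{receptor_a},
#' \code{receptor_b}) followed by one column per ordered cell-type pair
#' \code{"A|B"}. Empty cells mean the interaction is not significant for
#' that cell-type pair and become weight 0.
#'
#' @param path Path to the tab-separated table.
#' @param cell_types Optional explicit ordered cell-type set; inferred from
#'   the \code{"A|B"} column headers when omitted.
#' @return A list of interaction records (class \code{"cpdb_records"}),
#'   each with \code{pair_id}, \code{partner_a}, \code{partner_b},
#'   \code{receptor_a}, \code{receptor_b} and \code{values} (named by
#'   \code{"A|B"} column); the cell-type set is carried as attribute
#'   \code{"cell_types"}.
#' @export
read_cellphonedb <- function(path, cell_types = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  # every column that is not a known v2 metadata column must be an "A|B"
  # cell-type-pair column
  known_meta <- c("id_cp_interaction", "interacting_pair", "partner_a",
                  "partner_b", "gene_a", "gene_b", "secreted", "receptor_a",
                  "receptor_b", "annotation_strategy", "is_integrin", "rank",
                  "means", "pvalues", "is_percentile")
  meta_cols <- intersect(names(df), known_meta)
  pair_cols <- setdiff(names(df), meta_cols)
  if (!"interacting_pair" %in% meta_cols)
    stop(sprintf("'%s': no 'interacting_pair' column", path), call. = FALSE)
  bad <- pair_cols[!grepl("|", pair_cols, fixed = TRUE)]
  if (length(bad) > 0)
    stop(sprintf("'%s': malformed cell-type-pair header(s): %s", path,
                 paste(bad, collapse = ", ")), call. = FALSE)
  if (length(pair_cols) == 0)
    stop(sprintf("'%s': no 'A|B' cell-type-pair columns found", path),
         call. = FALSE)
  split_cols <- strsplit(pair_cols, "|", fixed = TRUE)
  long <- pair_cols[lengths(split_cols) != 2]
  if (length(long) > 0)
    stop(sprintf("'%s': malformed cell-type-pair header(s): %s", path,
                 paste(long, collapse = ", ")), call. = FALSE)
  senders <- trimws(vapply(split_cols, `[`, character(1), 1))
  receivers <- trimws(vapply(split_cols, `[`, character(1), 2))
  inferred <- unique(c(rbind(senders, receivers)))
  if (is.null(cell_types)) {
    cell_types <- cell_type_set(sort(inferred))
  } else {
    cell_types <- cell_type_set(cell_types)
    extra <- setdiff(inferred, cell_types)
    if (length(extra) > 0)
      stop(sprintf("'%s': column label(s) not in the declared cell types: %s",
                   path, paste(extra, collapse = ", ")), call. = FALSE)
  }
  as_flag <- function(x) {
    if (is.null(x)) return(rep(FALSE, nrow(df)))
    tolower(as.character(x)) %in% c("true", "t", "1", "yes")
  }
  ra <- as_flag(df[["receptor_a"]])
  rb <- as_flag(df[["receptor_b"]])
  records <- lapply(seq_len(nrow(df)), function(i) {
    vals <- suppressWarnings(as.numeric(df[i, pair_cols]))
    vals[is.na(vals)] <- 0
    if (any(vals < 0))
      stop(sprintf("'%s': negative weight in row %d", path, i), call. = FALSE)
    names(vals) <- pair_cols
    list(pair_id = trimws(df$interacting_pair[i]),
         partner_a = if ("partner_a" %in% meta_cols) df$partner_a[i] else NA_character_,
         partner_b = if ("partner_b" %in% meta_cols) df$partner_b[i] else NA_character_,
         receptor_a = ra[i], receptor_b = rb[i],
         values = vals)
  })
  structure(records, class = "cpdb_records", cell_types = cell_types)
}

#' Read the CellPhoneDB means + p-values dialect
#'
#' Two parallel tables with identical layout; a cell's mean becomes the
#' weight wherever the matching p-value is at most \code{p_threshold},
#' otherwise 0.
#'
#' @param means_path,pvalues_path Paths to the two tab-separated tables.
#' @param p_threshold Significance threshold on the p-value (default 0.05).
#' @param cell_types Optional explicit ordered cell-type set.
#' @return A \code{"cpdb_records"} list as in [read_cellphonedb()].
#' @export
read_cellphonedb_pvalues <- function(means_path, pvalues_path,
                                     p_threshold = 0.05, cell_types = NULL) {
  means <- read_cellphonedb(means_path, cell_types)
  pvals <- read_cellphonedb(pvalues_path, cell_types)
  pv_ids <- vapply(pvals, `[[`, character(1), "pair_id")
  for (i in seq_along(means)) {
    j <- match(means[[i]]$pair_id, pv_ids)
    if (is.na(j))
      stop(sprintf("interaction '%s' missing from the p-value table",
                   means[[i]]$pair_id), call. = FALSE)
    p <- pvals[[j]]$values[names(means[[i]]$values)]
    means[[i]]$values[is.na(p) | p > p_threshold] <- 0
  }
  means
}

#' Convert interaction records into a multiplex network
#'
#' One layer per interaction. Direction: when exactly one partner is
#' flagged as the receptor, edges run from the cell type expressing the
#' ligand to the cell type expressing the receptor (a value in column
#' \code{"i|j"} sits with partner a expressed by \code{i} and partner b by
#' \code{j}); when neither or both partners are receptors, the layer is
#' non-directional by biology and edges run P1-expresser to P2-expresser
#' exactly as the columns read. Interactions significant nowhere (all-zero
#' matrices) are dropped with a warning.
#'
#' @param records A [read_cellphonedb()] result.
#' @param cell_types Optional override of the record set's cell types.
#' @return A [build_multiplex()] network.
#' @export
records_to_layers <- function(records, cell_types = NULL) {
  stopifnot(inherits(records, "cpdb_records"))
  if (is.null(cell_types)) cell_types <- attr(records, "cell_types")
  cell_types <- cell_type_set(cell_types)
  n <- length(cell_types)
  layers <- list()
  dropped <- character(0)
  for (rec in records) {
    w <- matrix(0, n, n, dimnames = list(cell_types, cell_types))
    cols <- strsplit(names(rec$values), "|", fixed = TRUE)
    a_side <- trimws(vapply(cols, `[`, character(1), 1))
    b_side <- trimws(vapply(cols, `[`, character(1), 2))
    bad <- setdiff(unique(c(a_side, b_side)), cell_types)
    if (length(bad) > 0)
      stop(sprintf("interaction '%s': value for unknown cell type(s): %s",
                   rec$pair_id, paste(bad, collapse = ", ")), call. = FALSE)
    directional <- xor(rec$receptor_a, rec$receptor_b)
    if (directional && rec$receptor_a) {
      # ligand is partner b: the b-expresser sends
      w[cbind(b_side, a_side)] <- rec$values
    } else {
      # ligand (or P1) is partner a: the a-expresser sends
      w[cbind(a_side, b_side)] <- rec$values
    }
    if (all(w == 0)) {
      dropped <- c(dropped, rec$pair_id)
    } else {
      layers[[length(layers) + 1L]] <-
        build_layer(rec$pair_id, w, cell_types, directional = directional)
    }
  }
  if (length(dropped) > 0)
    warning(sprintf("dropped %d interaction(s) significant nowhere: %s",
                    length(dropped), paste(dropped, collapse = ", ")),
            call. = FALSE)
  if (length(layers) == 0)
    stop("no interaction is significant anywhere; nothing to build",
         call. = FALSE)
  build_multiplex(layers, cell_types)
}
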