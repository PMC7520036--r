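#' Compare communication patterns between two conditions
#'
#' For every interacting pair present in both networks (matched by pair id
#' after trimming whitespace), the weighted layer dissimilarity between the
#' two conditions is computed and the shared pairs are sorted by decreasing
#' dissimilarity: from the pairs whose communication pattern changes the
#' most across conditions to those that remain unaltered. Pairs present in
#' only one condition are reported separately rather than silently dropped
#' or conflated with "maximally changed"; set \code{exclusive_as_max} to
#' fold them into the ranking with dissimilarity 1.
#'
#' @param net_a,net_b Two [build_multiplex()] networks over an identical
#'   cell-type set (same labels, same order).
#' @param exclusive_as_max If \code{TRUE}, condition-exclusive pairs are
#'   appended to the ranking with dissimilarity 1.
#' @return Object of class \code{"ccc_comparison"}: list with
#'   \code{shared} (a descending [search_pattern()]-style ranking),
#'   \code{only_in_a}, \code{only_in_b} (character vectors, sorted).
#' @export
compare_conditions <- function(net_a, net_b, exclusive_as_max = FALSE) {
  stopifnot(inherits(net_a, "ccc_network"), inherits(net_b, "ccc_network"))
  if (!identical(net_a$cell_types, net_b$cell_types))
    stop("the two conditions must share the same cell types, in the same order",
         call. = FALSE)
  ids_a <- pair_ids(net_a)
  ids_b <- pair_ids(net_b)
  shared_ids <- intersect(ids_a, ids_b)
  only_a <- sort(setdiff(ids_a, ids_b))
  only_b <- sort(setdiff(ids_b, ids_a))
  d <- vapply(shared_ids, function(id)
    layer_dissimilarity(net_a$layers[[id]], net_b$layers[[id]]), double(1))
  ids <- shared_ids
  status <- rep("shared", length(ids))
  if (exclusive_as_max) {
    ids <- c(ids, only_a, only_b)
    d <- c(d, rep(1, length(only_a) + length(only_b)))
    status <- c(status, rep("only_in_a", length(only_a)),
                rep("only_in_b", length(only_b)))
  }
  ranking <- if (length(ids) > 0) {
    r <- ranking_table(ids, unname(d), decreasing = TRUE)
    r$status <- status[match(r$pair_id, ids)]
    r
  } else {
    r <- data.frame(rank = integer(0), pair_id = character(0),
                    dissimilarity = double(0), status = character(0))
    class(r) <- c("ccc_ranking", "data.frame")
    attr(r, "order") <- "descending"
    r
  }
  structure(list(shared = ranking, only_in_a = only_a, only_in_b = only_b),
            class = "ccc_comparison")
}

#' @export
print.ccc_comparison <- function(x, ...) {
  cat(sprintf("<condition comparison> %d shared, %d only in A, %d only in B\n",
              sum(x$shared$status == "shared"),
              length(x$only_in_a), length(x$only_in_b)))
  print(x$shared)
  invisible(x)
}
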