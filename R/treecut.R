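# Hybrid dynamic tree cut (Dynamic Hybrid of Langfelder, Zhang & Horvath,
# Bioinformatics 2008) on an hclust tree plus the dissimilarity matrix it
# was built from.
#
# Stage 1 walks the merge list below an adaptive cut height, growing basic
# branches and deciding at every branch-branch merge whether the smaller
# branch is a genuine cluster or should be absorbed. A basic branch is kept
# as a cluster when it (i) has at least min_cluster_size members, (ii) has a
# tight core (mean within-core dissimilarity below a deepSplit-controlled
# bound) and (iii) is separated from the rest of the tree by a minimum gap
# between its attachment height and its core scatter.
# Stage 2 assigns leftover objects (and, optionally, whole branches that
# failed only the size criterion) to the nearest cluster by average
# dissimilarity, PAM-style, within the same sub-tree when
# pam_respects_dendro is set. Objects that cannot be placed keep label 0.

# Core of a branch: the first objects to have joined, their number growing
# with branch size but sublinearly.
core_size <- function(branch_size, min_cluster_size) {
  base <- min_cluster_size / 2 + 1
  if (base < branch_size) {
    as.integer(base + sqrt(branch_size - base))
  } else {
    as.integer(branch_size)
  }
}

# mean, over core members, of their average dissimilarity to the other
# core members
core_scatter <- function(members, dmat) {
  k <- length(members)
  if (k < 2) return(0)
  sub <- dmat[members, members, drop = FALSE]
  mean(colSums(sub) / (k - 1))
}

#' Hybrid dynamic cut of a dendrogram
#'
#' Adaptive dendrogram cutting in the Dynamic Hybrid style: clusters are
#' branches of the average-linkage tree that are large enough, internally
#' tight and well separated; remaining objects are assigned to the nearest
#' cluster by average dissimilarity or left unassigned (label 0).
#'
#' @param dendro An \code{\link[stats]{hclust}} tree.
#' @param dist_matrix The square dissimilarity matrix the tree was built
#'   from (object order must match the tree's leaves).
#' @param deep_split Integer 0..4; 0 (the default used throughout this
#'   package) is the most conservative setting, producing the coarsest,
#'   best-separated clusters. Internally mapped to the maximum tolerated
#'   core scatter (0.64, 0.73, 0.82, 0.91, 0.95 of the height range above
#'   the 5\% reference height) and a minimum gap of 3/4 of the remaining
#'   headroom.
#' @param min_cluster_size Minimum number of members of a reported cluster.
#' @param cut_height Maximum joining height considered; defaults to 99\% of
#'   the height range above the 5\% reference height.
#' @param pam_stage If \code{TRUE} (default), unassigned objects are given
#'   to the closest cluster by mean dissimilarity when that distance is
#'   below \code{max_pam_dist}.
#' @param pam_respects_dendro If \code{TRUE} (default), the PAM-like stage
#'   only considers clusters lying in the same sub-tree (connected
#'   component of merges below the cut height) as the object.
#' @param max_pam_dist Maximum mean dissimilarity for PAM assignment;
#'   defaults to \code{cut_height}.
#' @param respect_small_clusters If \code{TRUE} (default), branches that
#'   failed only the size criterion are kept together and assigned to a
#'   cluster as a block when close enough, instead of being scattered.
#' @return Integer vector of cluster labels (0 = unassigned), named by the
#'   tree's labels when present, with attribute \code{"n_clusters"}.
#' @export
cutree_hybrid <- function(dendro, dist_matrix,
                          deep_split = 0, min_cluster_size = 6,
                          cut_height = NULL,
                          pam_stage = TRUE, pam_respects_dendro = TRUE,
                          max_pam_dist = NULL,
                          respect_small_clusters = TRUE) {
  stopifnot(inherits(dendro, "hclust"))
  if (!is.numeric(deep_split) || length(deep_split) != 1 ||
      deep_split != as.integer(deep_split) || deep_split < 0 || deep_split > 4)
    stop("deep_split must be an integer in 0..4", call. = FALSE)
  if (!is.numeric(min_cluster_size) || length(min_cluster_size) != 1 ||
      min_cluster_size < 1)
    stop("min_cluster_size must be a positive integer", call. = FALSE)
  min_cluster_size <- as.integer(min_cluster_size)
  dmat <- as.matrix(dist_matrix)
  n <- length(dendro$order)
  if (nrow(dmat) != n)
    stop("dist_matrix dimension does not match the tree", call. = FALSE)

  heights <- dendro$height
  merge <- dendro$merge
  n_merge <- length(heights)
  labels_out <- integer(n)
  finish <- function(lab) {
    if (!is.null(dendro$labels)) names(lab) <- dendro$labels
    k <- length(unique(lab[lab > 0]))
    attr(lab, "n_clusters") <- k
    lab
  }

  ref_merge <- max(1L, round(n_merge * 0.05))
  ref_height <- heights[ref_merge]
  if (is.null(cut_height)) {
    cut_height <- 0.99 * (max(heights) - ref_height) + ref_height
  } else {
    cut_height <- min(cut_height, max(heights))
  }
  if (is.null(max_pam_dist)) max_pam_dist <- cut_height
  if (sum(heights <= cut_height) < min_cluster_size)
    return(finish(labels_out))

  max_core_scatter <- c(0.64, 0.73, 0.82, 0.91, 0.95)[deep_split + 1]
  min_gap <- (1 - max_core_scatter) * 3 / 4
  max_abs_core_scatter <- ref_height + max_core_scatter * (cut_height - ref_height)
  min_abs_gap <- min_gap * (cut_height - ref_height)

  # branch bookkeeping
  max_br <- 2L * n
  is_basic <- logical(max_br)       # basic branch (owns singletons)
  is_top <- logical(max_br)         # not absorbed into another basic branch
  br_size <- integer(max_br)
  attach_h <- rep(NA_real_, max_br)
  singletons <- vector("list", max_br)
  sing_h <- vector("list", max_br)
  n_br <- 0L
  merge_to_branch <- integer(n_merge)
  # branches absorbed because they were too small; kept for block assignment
  small_blocks <- list()

  basic_scatter <- function(b) {
    cs <- core_size(length(singletons[[b]]), min_cluster_size)
    core_scatter(singletons[[b]][seq_len(cs)], dmat)
  }

  for (i in seq_len(n_merge)) {
    h <- heights[i]
    if (h > cut_height) next
    kids <- merge[i, ]
    kid_br <- integer(2)
    for (k in 1:2) {
      if (kids[k] > 0) {
        kid_br[k] <- merge_to_branch[kids[k]]
        if (kid_br[k] == 0L) kid_br[k] <- -1L  # child merged above the cut
      }
    }
    if (any(kid_br == -1L)) next

    if (all(kids < 0)) {                    # two singletons -> new basic branch
      n_br <- n_br + 1L
      is_basic[n_br] <- TRUE
      is_top[n_br] <- TRUE
      singletons[[n_br]] <- c(-kids[1], -kids[2])
      sing_h[[n_br]] <- c(h, h)
      br_size[n_br] <- 2L
      merge_to_branch[i] <- n_br
    } else if (any(kids < 0)) {             # singleton joins a branch
      b <- kid_br[kids > 0]
      s <- -kids[kids < 0]
      if (is_basic[b]) {
        singletons[[b]] <- c(singletons[[b]], s)
        sing_h[[b]] <- c(sing_h[[b]], h)
      }
      br_size[b] <- br_size[b] + 1L
      merge_to_branch[i] <- b
    } else {                                # branch meets branch
      b1 <- kid_br[1]; b2 <- kid_br[2]
      if (br_size[b1] <= br_size[b2]) { small <- b1; large <- b2 } else { small <- b2; large <- b1 }
      sc_small <- if (is_basic[small]) basic_scatter(small) else 0
      sc_large <- if (is_basic[large]) basic_scatter(large) else 0

      do_merge <- FALSE
      if (is_basic[small] &&
          (br_size[small] < min_cluster_size || sc_small > max_abs_core_scatter)) {
        do_merge <- TRUE
      } else if (is_basic[large] &&
                 (br_size[large] < min_cluster_size || sc_large > max_abs_core_scatter)) {
        tmp <- small; small <- large; large <- tmp
        sc_small <- sc_large
        do_merge <- TRUE
      }

      if (do_merge) {                       # absorb the failing branch
        fails_size_only <- br_size[small] < min_cluster_size &&
          sc_small <= max_abs_core_scatter
        if (fails_size_only && is_basic[small])
          small_blocks[[length(small_blocks) + 1L]] <-
            list(objects = singletons[[small]], absorbed = is_basic[large])
        if (is_basic[large] && is_basic[small]) {
          singletons[[large]] <- c(singletons[[large]], singletons[[small]])
          sing_h[[large]] <- c(sing_h[[large]],
                               rep(h, length(singletons[[small]])))
        }
        is_top[small] <- FALSE
        attach_h[small] <- h
        br_size[large] <- br_size[large] + br_size[small]
        merge_to_branch[i] <- large
      } else {                              # both survive; wrap in composite
        n_br <- n_br + 1L
        is_basic[n_br] <- FALSE
        is_top[n_br] <- TRUE
        br_size[n_br] <- br_size[b1] + br_size[b2]
        attach_h[b1] <- h
        attach_h[b2] <- h
        merge_to_branch[i] <- n_br
      }
    }
  }

  # evaluate surviving basic branches against the cluster criteria
  cand <- which(is_basic[seq_len(n_br)] & is_top[seq_len(n_br)])
  clusters <- list()
  for (b in cand) {
    ah <- attach_h[b]
    if (is.na(ah)) ah <- cut_height
    sc <- basic_scatter(b)
    sz <- length(singletons[[b]])
    ok <- sz >= min_cluster_size && sc < max_abs_core_scatter &&
      (ah - sc) > min_abs_gap
    if (ok) {
      clusters[[length(clusters) + 1L]] <- singletons[[b]]
    } else if (sz < min_cluster_size && sc <= max_abs_core_scatter) {
      small_blocks[[length(small_blocks) + 1L]] <-
        list(objects = singletons[[b]], absorbed = FALSE)
    }
  }
  if (length(clusters) == 0L) return(finish(labels_out))

  # stable numbering: by decreasing size, then by earliest member
  ord <- order(-vapply(clusters, length, integer(1)),
               vapply(clusters, min, double(1)))
  clusters <- clusters[ord]
  for (k in seq_along(clusters)) labels_out[clusters[[k]]] <- k

  # connected components of merges below the cut (sub-trees), for the
  # dendrogram-respecting PAM stage: walk merges tracking one representative
  # object per merge node and union components of merges below the cut
  comp <- seq_len(n)
  find <- function(x) { while (comp[x] != x) { comp[x] <<- comp[comp[x]]; x <- comp[x] }; x }
  rep_obj <- integer(n_merge)
  for (i in seq_len(n_merge)) {
    kids <- merge[i, ]
    reps <- ifelse(kids < 0, -kids, rep_obj[pmax(kids, 1L)])
    rep_obj[i] <- reps[1]
    if (heights[i] <= cut_height && all(reps > 0)) {
      r1 <- find(reps[1]); r2 <- find(reps[2])
      if (r1 != r2) comp[r2] <- r1
    }
  }
  obj_comp <- vapply(seq_len(n), find, integer(1))
  clus_comp <- vapply(clusters, function(m) obj_comp[m[1]], integer(1))

  mean_dist_to <- function(objs, members) mean(dmat[objs, members, drop = FALSE])

  if (pam_stage && respect_small_clusters && length(small_blocks) > 0) {
    for (blk in small_blocks) {
      objs <- blk$objects
      objs <- objs[labels_out[objs] == 0L]
      if (length(objs) == 0) next
      cand_k <- seq_along(clusters)
      if (pam_respects_dendro)
        cand_k <- cand_k[clus_comp == obj_comp[objs[1]]]
      if (length(cand_k) == 0) next
      dd <- vapply(cand_k, function(k) mean_dist_to(objs, clusters[[k]]), double(1))
      if (min(dd) < max_pam_dist)
        labels_out[objs] <- cand_k[which.min(dd)]
    }
  }

  if (pam_stage) {
    for (o in which(labels_out == 0L)) {
      cand_k <- seq_along(clusters)
      if (pam_respects_dendro)
        cand_k <- cand_k[clus_comp == obj_comp[o]]
      if (length(cand_k) == 0) next
      dd <- vapply(cand_k, function(k) mean_dist_to(o, clusters[[k]]), double(1))
      if (min(dd) < max_pam_dist)
        labels_out[o] <- cand_k[which.min(dd)]
    }
  }

  finish(labels_out)
}
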