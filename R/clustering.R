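# Threshold clustering of a phylogeny and two-stage representative selection:
# (1) split the tree into clusters whose leaf-pair patristic diameter does not
#     exceed a threshold (TreeCluster-style "max_clade" or "max" modes),
# (2) split each cluster into subclusters by hierarchical clustering on the
#     patristic sub-matrix, with the subcluster count set to a fraction of the
#     cluster size (20% in the reference screen),
# (3) pick one representative per subcluster, privileging user-declared
#     priority leaves (reference strains, previously tested sequences), then
#     the subcluster medoid, then the lexicographically smallest label.

# ---- internal tree bookkeeping ------------------------------------------------

tree_children <- function(tree) {
  n_node <- ape::Ntip(tree) + tree$Nnode
  kids <- vector("list", n_node)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]
    kids[[p]] <- c(kids[[p]], tree$edge[i, 2])
  }
  kids
}

tree_edge_len <- function(tree) {
  len <- numeric(ape::Ntip(tree) + tree$Nnode)
  len[tree$edge[, 2]] <- tree$edge.length
  len
}

# tip indices (1..Ntip) descending from every node, in tip.label order
tip_descendants <- function(tree) {
  ntip <- ape::Ntip(tree)
  kids <- tree_children(tree)
  desc <- vector("list", ntip + tree$Nnode)
  post <- rev(unique(ape::reorder.phylo(tree, "cladewise")$edge[, 1]))
  for (i in seq_len(ntip)) desc[[i]] <- i
  for (nd in post) {
    desc[[nd]] <- sort(unlist(lapply(kids[[nd]], function(k) desc[[k]])))
  }
  desc
}

clade_diameter <- function(tips, m_idx) {
  if (length(tips) < 2L) return(0)
  max(m_idx[tips, tips])
}

#' Threshold clustering of tree leaves
#'
#' Partitions the leaves so that the maximum pairwise patristic distance
#' within each cluster does not exceed `threshold`, in one of two
#' TreeCluster-style modes:
#'
#' * `"max_clade"` (default): clusters are the maximal clades whose leaf-pair
#'   diameter is at most the threshold, found bottom-up — a clade is kept
#'   whole iff its diameter fits, otherwise its children are examined.
#'   Clusters are always clades of the tree as written (rooting matters).
#' * `"max"`: the minimum number of clusters subject to the same diameter
#'   constraint, found by a single post-order pass that cuts the deeper child
#'   subtree whenever two subtrees can no longer be merged (ties broken toward
#'   the lower post-order child).
#'
#' @param tree A `phylo` object.
#' @param threshold Maximum within-cluster patristic diameter, in branch
#'   length units (the reference analysis used 1.75 substitutions/site).
#' @param mode `"max_clade"` or `"max"`.
#' @param matrix Optional precomputed patristic matrix (for reuse).
#' @return A tibble with columns `leaf` and `cluster` (integer ids contiguous
#'   from 1, numbered by the first member's position in the tree's tip order),
#'   one row per leaf, carrying `threshold` and `mode` as attributes.
#' @export
#' @examples
#' tr <- read_newick("((A:1,B:1):5,(C:1,D:1):5);")
#' threshold_clusters(tr, threshold = 3, mode = "max")
threshold_clusters <- function(tree, threshold, mode = c("max_clade", "max"),
                               matrix = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop("`threshold` must be a single positive number", call. = FALSE)
  }
  tree <- validate_tree(tree)
  m <- if (is.null(matrix)) patristic_matrix(tree) else as_patristic(matrix)
  labs <- tree$tip.label
  if (!setequal(rownames(m), labs)) {
    stop("matrix leaves do not match tree leaves", call. = FALSE)
  }
  m <- m[labs, labs, drop = FALSE]
  ntip <- ape::Ntip(tree)
  if (ntip == 1L) {
    return(new_cluster_tbl(labs, 1L, threshold, mode))
  }
  clusters <- switch(mode,
    max_clade = clusters_max_clade(tree, m, threshold),
    max = clusters_max(tree, m, threshold)
  )
  # number clusters by first member in tip order, ids contiguous from 1
  first <- vapply(clusters, min, integer(1))
  clusters <- clusters[order(first)]
  leaf_cluster <- integer(ntip)
  for (k in seq_along(clusters)) leaf_cluster[clusters[[k]]] <- k
  new_cluster_tbl(labs, leaf_cluster, threshold, mode)
}

new_cluster_tbl <- function(labs, cluster, threshold, mode) {
  out <- tibble::tibble(leaf = labs, cluster = as.integer(cluster))
  attr(out, "threshold") <- threshold
  attr(out, "mode") <- mode
  out
}

clusters_max_clade <- function(tree, m, threshold) {
  kids <- tree_children(tree)
  desc <- tip_descendants(tree)
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  out <- list()
  recurse <- function(nd) {
    tips <- desc[[nd]]
    if (clade_diameter(tips, m) <= threshold) {
      out[[length(out) + 1L]] <<- tips
    } else {
      for (k in kids[[nd]]) recurse(k)
    }
  }
  recurse(root)
  out
}

# Post-order greedy for mode "max": each node carries the set of still-active
# leaves below it and the largest distance from the node down to any of them.
# When the two deepest child contributions cannot coexist (their depth sum
# exceeds the threshold), the deeper child's active leaves are emitted as a
# finished cluster; ties cut the lower post-order child.
clusters_max <- function(tree, m, threshold) {
  ntip <- ape::Ntip(tree)
  kids <- tree_children(tree)
  elen <- tree_edge_len(tree)
  post <- rev(unique(ape::reorder.phylo(tree, "cladewise")$edge[, 1]))
  n_node <- ntip + tree$Nnode
  depth <- rep(-Inf, n_node)
  active <- vector("list", n_node)
  postidx <- integer(n_node)
  postidx[post] <- seq_along(post) + ntip
  postidx[seq_len(ntip)] <- seq_len(ntip)
  depth[seq_len(ntip)] <- 0
  # guard against float noise when a pairwise sum sits exactly on the threshold
  eps <- 1e-9 * max(1, threshold)
  for (i in seq_len(ntip)) active[[i]] <- i
  out <- list()
  for (nd in post) {
    ch <- kids[[nd]]
    d <- elen[ch] + depth[ch]
    alive <- which(is.finite(d))
    while (length(alive) >= 2L) {
      ord <- alive[order(-d[alive], postidx[ch[alive]])]
      a <- ord[1]; b <- ord[2]
      if (d[a] + d[b] <= threshold + eps) break
      out[[length(out) + 1L]] <- active[[ch[a]]]
      d[a] <- -Inf
      alive <- setdiff(alive, a)
    }
    if (length(alive) == 0L) {
      depth[nd] <- -Inf
    } else {
      depth[nd] <- max(d[alive])
      active[[nd]] <- sort(unlist(active[ch[alive]]))
    }
  }
  root <- ntip + 1L
  if (is.finite(depth[root])) out[[length(out) + 1L]] <- active[[root]]
  out
}

#' Plan subclusters within one cluster
#'
#' Agglomerative hierarchical clustering ([stats::hclust]) on the patristic
#' sub-matrix of a cluster's leaves, cut to `k = max(1, ceiling(fraction * n))`
#' subclusters (never more than n). Leaves are ordered lexicographically
#' before clustering so that merge ties resolve deterministically toward the
#' smaller member-label pair.
#'
#' @param leaves Character vector of leaf labels forming one cluster.
#' @param matrix Patristic matrix (or tree) covering those leaves.
#' @param fraction Target subcluster fraction of cluster size, in (0, 1];
#'   the reference screen used 0.2.
#' @param linkage `"average"` (default), `"complete"`, or `"single"`.
#' @return A tibble with columns `leaf` and `subcluster` (1..k).
#' @export
plan_subclusters <- function(leaves, matrix, fraction = 0.2,
                             linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  if (length(leaves) == 0L) stop("empty cluster", call. = FALSE)
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stop("`fraction` must be in (0, 1]", call. = FALSE)
  }
  m <- as_patristic(matrix)
  missing <- setdiff(leaves, rownames(m))
  if (length(missing)) {
    stop("cluster leaves absent from matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  n <- length(leaves)
  k <- min(max(1L, as.integer(ceiling(fraction * n))), n)
  labs <- sort(leaves)
  if (k == 1L || n == 1L) {
    sub <- stats::setNames(rep(1L, n), labs)
  } else {
    hc <- stats::hclust(stats::as.dist(m[labs, labs]), method = linkage)
    sub <- stats::cutree(hc, k = k)
  }
  tibble::tibble(leaf = labs, subcluster = as.integer(sub[labs]))
}

#' Pick one representative per subcluster
#'
#' Selection order within each subcluster: the member with the highest
#' priority rank (when that maximum is unique); otherwise the subcluster
#' medoid (minimum summed patristic distance to the other members); remaining
#' ties go to the lexicographically smallest label. `selection_reason` records
#' which rule fired.
#'
#' @param plan A tibble with columns `leaf`, `subcluster` and optionally
#'   `cluster` (as produced by [plan_subclusters()] / [sample_tree()]).
#' @param matrix Patristic matrix (or tree).
#' @param priorities Optional priority spec: a two-column data frame
#'   (`leaf`, `rank`) or a named numeric vector; higher rank = preferred;
#'   leaves not listed rank 0. The reference convention is reference strain =
#'   2, previously tested sequence = 1.
#' @return A tibble with one row per subcluster: `leaf`, (`cluster`,)
#'   `subcluster`, `selection_reason`.
#' @export
pick_representatives <- function(plan, matrix, priorities = NULL) {
  m <- as_patristic(matrix)
  rank_of <- priority_lookup(priorities)
  group_cols <- intersect(c("cluster", "subcluster"), names(plan))
  if (!"subcluster" %in% group_cols) stop("`plan` needs a subcluster column", call. = FALSE)
  plan |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
    dplyr::group_modify(function(df, key) select_representative(df$leaf, m, rank_of)) |>
    dplyr::ungroup() |>
    dplyr::relocate(dplyr::all_of("leaf"))
}

priority_lookup <- function(priorities) {
  if (is.null(priorities)) return(function(leaf) rep(0, length(leaf)))
  if (is.data.frame(priorities)) {
    if (!all(c("leaf", "rank") %in% names(priorities))) {
      stop("`priorities` data frame needs columns `leaf` and `rank`", call. = FALSE)
    }
    v <- stats::setNames(as.numeric(priorities$rank), priorities$leaf)
  } else if (is.numeric(priorities) && !is.null(names(priorities))) {
    v <- priorities
  } else {
    stop("`priorities` must be a (leaf, rank) data frame or named numeric vector",
         call. = FALSE)
  }
  if (any(v < 0)) stop("priority ranks must be non-negative", call. = FALSE)
  function(leaf) {
    out <- unname(v[leaf])
    out[is.na(out)] <- 0
    out
  }
}

select_representative <- function(members, m, rank_of) {
  ranks <- rank_of(members)
  top <- members[ranks == max(ranks)]
  if (length(top) == 1L && length(members) > 1L && max(ranks) > min(ranks)) {
    return(tibble::tibble(leaf = top, selection_reason = "priority"))
  }
  sums <- vapply(top, function(l) sum(m[l, setdiff(members, l)]), numeric(1))
  best <- top[sums == min(sums)]
  if (length(best) == 1L) {
    return(tibble::tibble(leaf = best, selection_reason = "medoid"))
  }
  tibble::tibble(leaf = min(best), selection_reason = "lexicographic")
}

#' Select a representative ortholog set from a tree
#'
#' End-to-end two-stage selection: threshold clustering
#' ([threshold_clusters()]), subclustering of each cluster to a fraction of
#' its size ([plan_subclusters()]), and one representative per subcluster
#' ([pick_representatives()]). Deterministic given its inputs.
#'
#' @inheritParams threshold_clusters
#' @inheritParams plan_subclusters
#' @inheritParams pick_representatives
#' @return A `representative_set` tibble with columns `leaf`, `cluster`,
#'   `subcluster`, `selection_reason`, one row per subcluster, ordered by
#'   (cluster, subcluster). A provenance list (params, per-cluster sizes and
#'   subcluster counts) is attached as attribute `"provenance"`; see
#'   [glance.representative_set()].
#' @export
#' @examples
#' tr <- read_newick("((A:1,B:1):5,(C:1,D:1):5);")
#' sample_tree(tr, threshold = 3, fraction = 0.5, mode = "max")
sample_tree <- function(tree, threshold = 1.75, fraction = 0.2,
                        mode = c("max_clade", "max"),
                        linkage = c("average", "complete", "single"),
                        priorities = NULL, matrix = NULL) {
  mode <- match.arg(mode)
  linkage <- match.arg(linkage)
  tree <- validate_tree(tree)
  m <- if (is.null(matrix)) patristic_matrix(tree) else as_patristic(matrix)
  cl <- threshold_clusters(tree, threshold, mode, matrix = m)
  plan <- cl |>
    dplyr::group_by(.data$cluster) |>
    dplyr::group_modify(function(df, key) {
      plan_subclusters(df$leaf, m, fraction = fraction, linkage = linkage)
    }) |>
    dplyr::ungroup()
  reps <- pick_representatives(plan, m, priorities) |>
    dplyr::arrange(.data$cluster, .data$subcluster)
  sizes <- cl |> dplyr::count(.data$cluster, name = "n_leaves")
  ks <- plan |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(n_subclusters = dplyr::n_distinct(.data$subcluster))
  out <- reps
  attr(out, "provenance") <- list(
    threshold = threshold, fraction = fraction, mode = mode, linkage = linkage,
    n_leaves = ape::Ntip(tree), n_clusters = nrow(sizes),
    clusters = dplyr::left_join(sizes, ks, by = "cluster"),
    assignment = plan
  )
  class(out) <- c("representative_set", class(out))
  out
}

#' @export
print.representative_set <- function(x, ...) {
  pv <- attr(x, "provenance")
  cat("Representative set: ", nrow(x), " leaves from ", pv$n_leaves,
      " (", pv$n_clusters, " clusters; mode=", pv$mode,
      ", threshold=", pv$threshold, ", fraction=", pv$fraction, ")\n", sep = "")
  NextMethod()
}

#' Tidy a representative set
#'
#' @param x A `representative_set`.
#' @param ... Unused.
#' @return The selection as a plain tibble.
#' @export
tidy.representative_set <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("leaf", "cluster", "subcluster", "selection_reason")])
}

#' One-row summary of a representative set
#'
#' @param x A `representative_set`.
#' @param ... Unused.
#' @return A one-row tibble: leaves in tree, clusters, selected count, params.
#' @export
glance.representative_set <- function(x, ...) {
  pv <- attr(x, "provenance")
  tibble::tibble(
    n_leaves = pv$n_leaves, n_clusters = pv$n_clusters, n_selected = nrow(x),
    threshold = pv$threshold, fraction = pv$fraction,
    mode = pv$mode, linkage = pv$linkage
  )
}

#' Write a representative set (and its cluster assignment) to TSV
#'
#' @param reps A `representative_set`.
#' @param file Path for the representatives TSV (`leaf`, `cluster`,
#'   `subcluster`, `selection_reason`).
#' @param assignment_file Optional path for the full leaf assignment TSV
#'   (`leaf`, `cluster`, `subcluster`).
#' @return `file`, invisibly.
#' @export
write_representatives_tsv <- function(reps, file, assignment_file = NULL) {
  readr::write_tsv(tidy.representative_set(reps), file)
  if (!is.null(assignment_file)) {
    readr::write_tsv(attr(reps, "provenance")$assignment, assignment_file)
  }
  invisible(file)
}
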