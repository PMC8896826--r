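# Independent oracles used across the suite. Deliberately naive and written
# against ape's raw edge matrix only, so they share no code path with the
# package implementations they check.

# Patristic distance by explicit root-path enumeration with parent pointers.
oracle_patristic <- function(tree) {
  ntip <- ape::Ntip(tree)
  n_node <- ntip + tree$Nnode
  parent <- rep(NA_integer_, n_node)
  plen <- rep(0, n_node)
  for (i in seq_len(nrow(tree$edge))) {
    parent[tree$edge[i, 2]] <- tree$edge[i, 1]
    plen[tree$edge[i, 2]] <- tree$edge.length[i]
  }
  path_to_root <- function(nd) {
    nodes <- nd; depth <- 0
    depths <- stats::setNames(0, nd)
    while (!is.na(parent[nd])) {
      depth <- depth + plen[nd]
      nd <- parent[nd]
      depths <- c(depths, stats::setNames(depth, nd))
    }
    depths # named: node -> distance from the starting leaf
  }
  paths <- lapply(seq_len(ntip), path_to_root)
  m <- matrix(0, ntip, ntip, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(ntip)) {
    for (j in seq_len(ntip)) {
      if (i == j) next
      common <- intersect(names(paths[[i]]), names(paths[[j]]))
      # the common ancestor nearest both leaves minimizes the summed distance
      m[i, j] <- min(paths[[i]][common] + paths[[j]][common])
    }
  }
  m
}

# All set partitions of a small vector (Bell-number growth; keep n <= 7).
all_set_partitions <- function(items) {
  if (length(items) == 1L) return(list(list(items)))
  rest <- all_set_partitions(items[-1L])
  out <- list()
  for (p in rest) {
    for (k in seq_along(p)) {
      q <- p
      q[[k]] <- c(items[1L], q[[k]])
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(list(items[1L]), p)
  }
  out
}

partition_ok <- function(partition, m, threshold) {
  all(vapply(partition, function(block) {
    length(block) < 2L || max(m[block, block]) <= threshold
  }, logical(1)))
}

# Global minimum cluster count over ALL leaf partitions with the diameter
# constraint (n <= 7).
oracle_min_partition <- function(m, threshold) {
  parts <- all_set_partitions(rownames(m))
  sizes <- vapply(parts, function(p) {
    if (partition_ok(p, m, threshold)) length(p) else Inf
  }, numeric(1))
  min(sizes)
}

# Minimum cluster count achievable by cutting tree edges (exhaustive over
# all 2^E cut sets; keep the tree small).
oracle_min_edge_cut <- function(tree, m, threshold) {
  ntip <- ape::Ntip(tree)
  n_node <- ntip + tree$Nnode
  E <- nrow(tree$edge)
  best <- Inf
  for (mask in 0:(2^E - 1)) {
    keep <- !as.logical(bitwAnd(mask, 2^(seq_len(E) - 1L)))
    comp <- seq_len(n_node)
    find <- function(x) { while (comp[x] != x) x <- comp[x]; x }
    for (i in seq_len(E)) {
      if (keep[i]) {
        a <- find(tree$edge[i, 1]); b <- find(tree$edge[i, 2])
        comp[a] <- b
      }
    }
    groups <- split(seq_len(ntip), vapply(seq_len(ntip), find, integer(1)))
    labs <- lapply(groups, function(g) tree$tip.label[g])
    if (partition_ok(labs, m, threshold)) best <- min(best, length(groups))
  }
  best
}

# Thresholds placed strictly between distinct pairwise-distance levels, so
# that diameter comparisons are unambiguous for implementation and oracle
# alike (pure-birth trees are ultrametric and heavily tied; a quantile of the
# distances would sit within float noise of a true distance).
mid_thresholds <- function(m, probs) {
  u <- sort(unique(round(m[m > 0], 9)))
  cand <- c(u[1] / 2,
            if (length(u) > 1) (u[-length(u)] + u[-1]) / 2,
            u[length(u)] * 1.1)
  cand[pmax(1L, ceiling(probs * length(cand)))]
}

# Exact minimum diameter-constrained partition by dynamic programming over
# leaf subsets (implicitly enumerates every partition; fine to ~12 leaves).
oracle_min_partition_dp <- function(m, threshold) {
  n <- nrow(m)
  full <- bitwShiftL(1L, n) - 1L
  valid <- logical(full + 1L)
  for (mask in 1:full) {
    idx <- which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1L))) != 0L)
    valid[mask + 1L] <- length(idx) < 2L || max(m[idx, idx]) <= threshold
  }
  dp <- rep(Inf, full + 1L)
  dp[1L] <- 0
  for (mask in 1:full) {
    low <- bitwAnd(mask, -mask) # lowest set bit must live in some block
    sub <- mask
    while (sub > 0L) {
      if (bitwAnd(sub, low) != 0L && valid[sub + 1L]) {
        dp[mask + 1L] <- min(dp[mask + 1L], dp[mask - sub + 1L] + 1)
      }
      sub <- bitwAnd(sub - 1L, mask)
    }
  }
  dp[full + 1L]
}

# max_clade clusters via the independent characterization: each leaf belongs
# to its highest ancestor whose descendant leaf-set diameter fits.
oracle_max_clade <- function(tree, m, threshold) {
  ntip <- ape::Ntip(tree)
  n_node <- ntip + tree$Nnode
  parent <- rep(NA_integer_, n_node)
  for (i in seq_len(nrow(tree$edge))) parent[tree$edge[i, 2]] <- tree$edge[i, 1]
  below <- function(nd) {
    if (nd <= ntip) return(nd)
    kids <- tree$edge[tree$edge[, 1] == nd, 2]
    sort(unlist(lapply(kids, below)))
  }
  cluster_of <- vapply(seq_len(ntip), function(leaf) {
    nd <- leaf; best <- leaf
    while (!is.na(parent[nd])) {
      nd <- parent[nd]
      tips <- tree$tip.label[below(nd)]
      if (max(m[tips, tips]) <= threshold) best <- nd else break
    }
    best
  }, integer(1))
  unname(split(tree$tip.label, cluster_of))
}

# Exact two-sided rank-sum p by brute-force enumeration over all
# choose(N, n1) assignments (mid-ranks for ties).
oracle_ranksum_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  W_obs <- sum(r[seq_len(n1)])
  combos <- utils::combn(length(pooled), n1)
  Ws <- apply(combos, 2, function(idx) sum(r[idx]))
  p_le <- mean(Ws <= W_obs + 1e-9)
  p_ge <- mean(Ws >= W_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Kruskal-Wallis H by the textbook tie-corrected formula.
oracle_kw_h <- function(groups) {
  vals <- unlist(groups)
  N <- length(vals)
  r <- rank(vals)
  idx <- rep(seq_along(groups), lengths(groups))
  Rc <- tapply(r, idx, sum)
  nc <- lengths(groups)
  H <- 12 / (N * (N + 1)) * sum(Rc^2 / nc) - 3 * (N + 1)
  ties <- table(vals)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Same-named partitions ignoring cluster ids/order.
canonical_partition <- function(df) {
  unname(lapply(split(df$leaf, df$cluster), sort)[
    order(vapply(split(df$leaf, df$cluster), function(x) sort(x)[1], character(1)))])
}

canonical_blocks <- function(blocks) {
  blocks <- lapply(blocks, sort)
  unname(blocks[order(vapply(blocks, `[`, character(1), 1))])
}
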