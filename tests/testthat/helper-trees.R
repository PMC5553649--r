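# Fixtures and independent oracles shared across test files.  Everything
# here deliberately avoids the package's own traversal code: distances
# come from ape::dist.nodes / cophenetic, triplet topologies from
# ape::keep.tip pruning.

star3 <- function() read_newick(text = "(A:1,B:3,C:4);")[[1]]

rand_tree <- function(n) {
  tr <- ape::rtree(n)
  tr$edge.length <- stats::rexp(nrow(tr$edge))
  tr
}

# Tips below the child endpoint of edge row k, by explicit path algebra:
# leaf i lies below v iff d(i,u) = d(i,v) + e.
tips_under <- function(dn, n, u, v, ev) {
  abs(dn[seq_len(n), u] - (dn[seq_len(n), v] + ev)) < 1e-9 * max(1, ev)
}

# Root-to-tip distance vector for a point at offset x from parent u on
# edge (u, v), from an all-pairs distance matrix.
point_tip_dists <- function(dn, n, u, v, ev, x, under = NULL) {
  if (is.null(under)) under <- tips_under(dn, n, u, v, ev)
  ifelse(under, dn[seq_len(n), v] + ev - x, dn[seq_len(n), u] + x)
}

# Quadratic-time minimax oracle: smallest achievable max tip distance
# over a uniform grid of candidate roots on every edge.
minimax_grid <- function(tree, grid = 60) {
  dn <- ape::dist.nodes(tree)
  n <- length(tree$tip.label)
  best <- Inf
  for (k in seq_len(nrow(tree$edge))) {
    u <- tree$edge[k, 1]; v <- tree$edge[k, 2]; ev <- tree$edge.length[k]
    under <- tips_under(dn, n, u, v, ev)
    for (x in seq(0, ev, length.out = grid)) {
      best <- min(best, max(point_tip_dists(dn, n, u, v, ev, x, under)))
    }
  }
  best
}

# Independent rooted-triplet oracle built on pruning: the resolved
# topology of a 3-leaf subtree is the pair whose MRCA is not the root.
oracle_triplet_topology <- function(tree, three) {
  sub <- ape::keep.tip(tree, three)
  root <- length(sub$tip.label) + 1L
  for (pr in list(c(1, 2), c(1, 3), c(2, 3))) {
    m <- ape::getMRCA(sub, sub$tip.label[pr])
    if (m != root) return(paste(sort(sub$tip.label[pr]), collapse = "|"))
  }
  "unresolved"
}

oracle_triplet_distance <- function(ref, est) {
  trip <- utils::combn(sort(ref$tip.label), 3)
  denom <- 0L; hit <- 0L
  for (j in seq_len(ncol(trip))) {
    a <- oracle_triplet_topology(ref, trip[, j])
    if (a == "unresolved") next
    denom <- denom + 1L
    if (identical(a, oracle_triplet_topology(est, trip[, j]))) hit <- hit + 1L
  }
  1 - hit / denom
}

# Locate a target point in `tree` from its tip-distance vector (named by
# labels); returns the root_position realizing those distances, or NULL.
position_from_tip_distances <- function(tree, target) {
  dn <- ape::dist.nodes(tree)
  n <- length(tree$tip.label)
  tgt <- as.numeric(target[tree$tip.label])
  for (k in seq_len(nrow(tree$edge))) {
    u <- tree$edge[k, 1]; v <- tree$edge[k, 2]; ev <- tree$edge.length[k]
    under <- tips_under(dn, n, u, v, ev)
    i1 <- which(under)[1]; i2 <- which(!under)[1]
    if (is.na(i1) || is.na(i2)) next
    x1 <- dn[i1, v] + ev - tgt[i1]
    x2 <- tgt[i2] - dn[i2, u]
    if (abs(x1 - x2) < 1e-8 && x1 > -1e-9 && x1 < ev + 1e-9) {
      x <- min(max(x1, 0), ev)
      d <- point_tip_dists(dn, n, u, v, ev, x, under)
      if (max(abs(d - tgt)) < 1e-6) return(root_position(v, x))
    }
  }
  NULL
}
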