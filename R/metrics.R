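## Rooted triplet topology codes for all C(n,3) leaf triples, with leaves
## taken in the order of `labels`.  Code 1 = ij|k, 2 = ik|j, 3 = jk|i
## (i < j < k in label order), 0 = unresolved (multifurcation).  Two
## rooted trees agree on a triple iff their codes are equal and nonzero.
triplet_codes <- function(tree, labels) {
  n <- length(labels)
  idx <- match(labels, tree$tip.label)
  tt <- tree_tables(tree)
  D <- node_edge_depths(tt)
  M <- ape::mrca(tt$tree)            # tip x tip MRCA node ids
  M <- M[idx, idx]
  cmb <- utils::combn(n, 3L)
  i <- cmb[1, ]; j <- cmb[2, ]; k <- cmb[3, ]
  dij <- D[M[cbind(i, j)]]
  dik <- D[M[cbind(i, k)]]
  djk <- D[M[cbind(j, k)]]
  code <- integer(ncol(cmb))
  code[dij > dik & dij > djk] <- 1L
  code[dik > dij & dik > djk] <- 2L
  code[djk > dij & djk > dik] <- 3L
  code
}

#' Rooted triplet distance between two trees on the same leaves
#'
#' The proportion of leaf triples whose induced rooted 3-leaf topology in
#' the reference tree is *not* found in the estimated tree.  A triple
#' that is unresolved (multifurcating) in the reference is excluded from
#' the denominator; a triple resolved in the reference but unresolved in
#' the estimate counts as a mismatch.  0 means the two rooted trees agree
#' on every resolved triple; for fully resolved trees the denominator is
#' `choose(n, 3)`.
#'
#' @param reference,estimate Rooted `phylo` trees over identical leaf
#'   label sets, `n >= 3`.
#' @return A number in `[0, 1]`.
#' @export
triplet_distance <- function(reference, estimate) {
  labels <- sort(reference$tip.label)
  if (!setequal(labels, estimate$tip.label) ||
      length(reference$tip.label) != length(estimate$tip.label))
    stop("trees must share an identical leaf label set")
  if (length(labels) < 3L) stop("triplet distance needs >= 3 leaves")
  rc <- triplet_codes(reference, labels)
  ec <- triplet_codes(estimate, labels)
  resolved <- rc != 0L
  denom <- sum(resolved)
  if (denom == 0L) {
    warning("reference tree resolves no triplets; returning NA")
    return(NA_real_)
  }
  1 - sum(resolved & ec == rc) / denom
}

#' Best achievable ("ideal") rooting of an estimated tree
#'
#' Tries rooting the estimated tree on every edge (the position along an
#' edge does not affect rooted triplet topologies; the midpoint is used)
#' and returns the rooting with the lowest triplet distance to the rooted
#' reference.  The minimum is 0 exactly when the estimate's *unrooted*
#' topology is correct, so subtracting it from a specific rooting's
#' triplet distance (the "delta triplet distance") isolates rooting error
#' from topological error.
#'
#' @param true_tree Rooted reference `phylo`.
#' @param estimate A `phylo` over the same leaves, in any orientation.
#' @return A list with `position` (a [root_position()] on `estimate`),
#'   `triplet_distance` (the minimum), and `tree` (the ideally rooted
#'   estimate).
#' @export
ideal_rooting <- function(true_tree, estimate) {
  best <- NULL
  for (k in seq_len(nrow(estimate$edge))) {
    pos <- root_position(estimate$edge[k, 2], estimate$edge.length[k] / 2)
    cand <- reroot_at(estimate, pos)
    d <- triplet_distance(true_tree, cand)
    if (is.null(best) || d < best$triplet_distance - 1e-12) {
      best <- list(position = pos, triplet_distance = d, tree = cand)
    }
  }
  best
}

#' Normalized branch distance between true and estimated root positions
#'
#' Counts the branches separating the estimated root point from the true
#' root on the *same* tree, normalized by the maximum number of branches
#' from the true root to any leaf.  Both points lying on the same edge
#' gives 0; otherwise the count is 1 plus the number of complete edges
#' strictly between them.  For a bifurcating true root, its two incident
#' edges form a single edge of the unrooted tree and are treated as the
#' root's host edge.  Used for scoring rooting methods on true
#' (simulated) gene trees, where the estimated root is a position on the
#' true tree itself.
#'
#' @param true_tree Rooted `phylo` carrying the true root.
#' @param estimated_root A [root_position()] on `true_tree` (e.g. from
#'   [minvar_root()] run on the same tree).
#' @return A number in `[0, 1]`.
#' @export
branch_distance <- function(true_tree, estimated_root) {
  rp <- resolve_position(true_tree, estimated_root)
  tt <- tree_tables(true_tree)
  ed <- node_edge_depths(tt)
  root_children <- tt$E[tt$E[, 1] == tt$root, 2]
  v <- rp$child
  if (length(root_children) == 2L) {
    ## binary root: host edge is the merged pair of root-incident edges
    d <- if (v %in% root_children) 0L else ed[rp$parent]
  } else {
    ## multifurcating root: true root is the node itself
    d <- ed[rp$parent]
  }
  maxdepth <- max(ed[seq_len(tt$n)])
  d / maxdepth
}

#' Unrooted Robinson-Foulds distance, normalized
#'
#' The symmetric difference between the two trees' non-trivial
#' bipartition sets, divided by `2n - 6` (the maximum for two fully
#' resolved unrooted trees on `n` leaves).
#'
#' @param tree1,tree2 `phylo` trees over identical leaf label sets,
#'   `n >= 4`.
#' @return A number in `[0, 1]` for binary trees (the numerator is
#'   reported against the binary maximum even if a tree has
#'   multifurcations).
#' @export
rf_distance <- function(tree1, tree2) {
  labels <- sort(tree1$tip.label)
  if (!setequal(labels, tree2$tip.label) ||
      length(tree1$tip.label) != length(tree2$tip.label))
    stop("trees must share an identical leaf label set")
  n <- length(labels)
  if (n < 4L) stop("unrooted RF distance needs >= 4 leaves")
  b1 <- bipartition_keys(tree1, labels)
  b2 <- bipartition_keys(tree2, labels)
  length(union(setdiff(b1, b2), setdiff(b2, b1))) / (2 * n - 6)
}

## Canonical keys for the non-trivial bipartitions of an unrooted tree:
## the side not containing the first label, as a sorted index string.
bipartition_keys <- function(tree, labels) {
  tt <- tree_tables(tree)
  n <- tt$n
  ord <- match(tt$tree$tip.label, labels)
  below <- vector("list", tt$N)
  for (i in seq_len(n)) below[[i]] <- ord[i]
  for (k in seq_len(nrow(tt$E))) {
    p <- tt$E[k, 1]; v <- tt$E[k, 2]
    below[[p]] <- c(below[[p]], below[[v]])
  }
  keys <- character(0)
  for (k in seq_len(nrow(tt$E))) {
    v <- tt$E[k, 2]
    if (v <= n) next                       # pendant edge: trivial
    s <- below[[v]]
    if (length(s) >= n - 1L) next          # trivial on the other side
    if (1L %in% s) s <- setdiff(seq_len(n), s)
    keys <- c(keys, paste(sort(s), collapse = ","))
  }
  unique(keys)
}

#' Score rootings of estimated trees against rooted references
#'
#' For each reference/estimate pair, roots the estimate with the
#' requested methods and reports the rooted triplet distance, the delta
#' triplet distance against the best achievable rooting of the same
#' estimate, the root-to-tip variance at the chosen root, and (when the
#' estimate shares the reference's unrooted topology) the normalized
#' branch distance of the chosen root from the true root.
#'
#' @param reference A rooted `phylo` or list of them.
#' @param estimate A `phylo` or list of them, aligned with `reference`.
#' @param methods Subset of `c("MV", "MP", "OG")`.
#' @param outgroup Leaf labels for the `"OG"` method.
#' @param compute_ideal Whether to search all rootings of each estimate
#'   for the ideal triplet distance (feasible at desk scale).
#' @param compute_branch Whether to attempt the branch distance (the
#'   estimate's root position is mapped onto the reference through the
#'   shared bipartition; skipped with `NA` when topologies differ).
#' @return A data.frame with columns `tree_index`, `method`,
#'   `triplet_distance`, `delta_triplet`, `branch_distance`,
#'   `root_variance`.
#' @export
evaluate_rootings <- function(reference, estimate,
                              methods = c("MV", "MP"), outgroup = NULL,
                              compute_ideal = TRUE, compute_branch = FALSE) {
  if (inherits(reference, "phylo")) reference <- list(reference)
  if (inherits(estimate, "phylo")) estimate <- list(estimate)
  if (length(reference) != length(estimate))
    stop("reference and estimate lists differ in length")
  if ("OG" %in% methods && is.null(outgroup))
    stop("method 'OG' requires `outgroup` labels")
  rows <- list()
  for (i in seq_along(reference)) {
    ref <- reference[[i]]; est <- estimate[[i]]
    ideal <- if (compute_ideal) ideal_rooting(ref, est)$triplet_distance
             else NA_real_
    for (meth in methods) {
      rt <- switch(meth,
                   MV = minvar_root(est),
                   MP = midpoint_root(est),
                   OG = outgroup_root(est, outgroup),
                   stop("unknown method: ", meth))
      td <- triplet_distance(ref, rt$tree)
      bd <- NA_real_
      if (compute_branch) {
        mapped <- map_position(est, rt$position, ref)
        if (!is.null(mapped)) bd <- branch_distance(ref, mapped)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        tree_index = i, method = meth, triplet_distance = td,
        delta_triplet = if (is.na(ideal)) NA_real_ else td - ideal,
        branch_distance = bd,
        root_variance = if (!is.null(rt$variance)) rt$variance
                        else pop_var(tip_distances(rt$tree)))
    }
  }
  do.call(rbind, rows)
}

## Map a root position on `from` onto the same unrooted edge of `to`
## (same unrooted topology assumed), matching edges by the leaf set they
## separate.  Returns NULL when no matching edge exists.
map_position <- function(from, pos, to) {
  rp <- resolve_position(from, pos)
  labels <- sort(from$tip.label)
  key_of <- function(tree, child) {
    tt <- tree_tables(tree)
    n <- tt$n
    ord <- match(tt$tree$tip.label, labels)
    below <- vector("list", tt$N)
    for (i in seq_len(n)) below[[i]] <- ord[i]
    for (k in seq_len(nrow(tt$E))) {
      p <- tt$E[k, 1]; v <- tt$E[k, 2]
      below[[p]] <- c(below[[p]], below[[v]])
    }
    canon <- function(s) {
      if (1L %in% s) s <- setdiff(seq_len(n), s)
      paste(sort(s), collapse = ",")
    }
    if (!is.null(child)) return(canon(below[[child]]))
    sapply(tt$E[, 2], function(v) canon(below[[v]]))
  }
  want <- key_of(from, rp$child)
  keys <- key_of(to, NULL)
  hit <- which(keys == want)
  if (length(hit) == 0L) return(NULL)
  child <- to$edge[hit[1], 2]
  elen <- to$edge.length[hit[1]]
  ## place proportionally along the matched edge; topology metrics do not
  ## depend on the offset
  frac <- if (rp$elen > 0) rp$offset / rp$elen else 0
  root_position(child, frac * elen)
}
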