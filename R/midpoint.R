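#' Linear-time midpoint (MP) rooting
#'
#' Roots the tree at the middle of the longest leaf-to-leaf path, the
#' point minimizing the maximum root-to-tip distance.  A post-order pass
#' computes `MI(u)`, the farthest leaf below each node; a pre-order pass
#' computes `MO`, the farthest leaf reachable through the parent.  The
#' midpoint lies on the edge `(u, v)` (with `u` the parent) where
#' `x = (MI(v) - MO + e_v) / 2` falls within `[0, e_v]`; `x` is the
#' offset from `u`.  When the midpoint sits exactly at a node, several
#' edges qualify and the first in pre-order is used (a deterministic
#' choice; all describe the same point of the unrooted tree).
#'
#' @inheritParams clade_stats
#' @return An object of class `tree_rooting`: a list with `method`
#'   (`"MP"`), `position`, `max_tip_distance` (equal to half the tree
#'   diameter), and `tree` (the rerooted `phylo`).
#' @examples
#' tr <- read_newick(text = "(A:1,B:3,C:4);")[[1]]
#' rt <- midpoint_root(tr)
#' rt$max_tip_distance   # 3.5 = diameter 7 / 2
#' @export
midpoint_root <- function(tree) {
  tt <- tree_tables(tree)
  E <- tt$E; len <- tt$len; n <- tt$n; N <- tt$N; m <- nrow(E)
  if (n < 2L) stop("midpoint rooting needs a tree with >= 2 leaves")

  ## post-order: max distance down to a leaf in the clade
  MI <- numeric(N)
  for (k in seq_len(m)) {
    p <- E[k, 1]; v <- E[k, 2]
    MI[p] <- max(MI[p], MI[v] + len[k])
  }

  ## pre-order: max distance to a leaf outside the clade, via the parent
  MO <- numeric(N)
  children <- split(seq_len(m), E[, 1])
  child_idx <- integer(N)
  child_idx[as.integer(names(children))] <- seq_along(children)
  found <- NULL
  for (k in rev(seq_len(m))) {
    u <- E[k, 1]; v <- E[k, 2]; ev <- len[k]
    sibs <- children[[child_idx[u]]]
    mo <- MO[u]
    for (s in sibs) {
      if (s != k) mo <- max(mo, MI[E[s, 2]] + len[s])
    }
    x <- (MI[v] - mo + ev) / 2
    if (is.null(found) && x >= 0 && x <= ev) {
      found <- list(child = v, x = x, half = (MI[v] + mo + ev) / 2)
    }
    MO[v] <- mo + ev
  }
  pos <- root_position(found$child, found$x)
  structure(list(method = "MP", position = pos,
                 max_tip_distance = found$half,
                 tree = reroot_at(tt$tree, pos)),
            class = "tree_rooting")
}

#' Tree diameter: the longest leaf-to-leaf path
#'
#' Computed exactly in linear time by taking, at every internal node, the
#' two deepest leaf paths entering from distinct children.
#'
#' @inheritParams clade_stats
#' @return A list with `diameter` (path length) and `leaves` (the labels
#'   of one pair of leaves realizing it).
#' @export
tree_diameter <- function(tree) {
  tt <- tree_tables(tree)
  E <- tt$E; len <- tt$len; n <- tt$n; N <- tt$N; m <- nrow(E)
  if (n < 2L) stop("tree diameter needs >= 2 leaves")
  MI <- numeric(N)
  MI_leaf <- integer(N)           # which leaf realizes MI
  MI_leaf[seq_len(n)] <- seq_len(n)
  best1 <- best2 <- numeric(N)    # two deepest child paths per node
  leaf1 <- leaf2 <- integer(N)
  best2[] <- -Inf
  for (k in seq_len(m)) {
    p <- E[k, 1]; v <- E[k, 2]
    d <- MI[v] + len[k]
    if (d >= best1[p]) {
      best2[p] <- best1[p]; leaf2[p] <- leaf1[p]
      best1[p] <- d; leaf1[p] <- MI_leaf[v]
    } else if (d > best2[p]) {
      best2[p] <- d; leaf2[p] <- MI_leaf[v]
    }
    if (d > MI[p]) { MI[p] <- d; MI_leaf[p] <- MI_leaf[v] }
  }
  internal <- unique(E[, 1])
  two <- internal[is.finite(best2[internal])]
  tot <- best1[two] + best2[two]
  i <- two[which.max(tot)]
  list(diameter = best1[i] + best2[i],
       leaves = tt$tree$tip.label[c(leaf1[i], leaf2[i])])
}
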