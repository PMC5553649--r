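#' A root position: a point on an edge of a tree
#'
#' Every rooting method in this package returns a point on an edge of the
#' input tree, encoded by the child endpoint of that edge (in the input
#' tree's node numbering, where each non-root node identifies the edge to
#' its parent) and the offset of the point from the *parent* endpoint
#' toward the child.  Offset 0 places the root exactly at the parent node,
#' offset equal to the edge length exactly at the child.
#'
#' @param child Node id (in `phylo` numbering) of the child endpoint of
#'   the edge carrying the root.
#' @param offset Distance of the root from the parent endpoint, in branch
#'   length units; must lie in `[0, edge length]`.
#' @return An object of class `root_position`.
#' @export
root_position <- function(child, offset) {
  stopifnot(length(child) == 1L, length(offset) == 1L,
            is.finite(child), is.finite(offset), offset >= 0)
  structure(list(child = as.integer(child), offset = as.numeric(offset)),
            class = "root_position")
}

#' @export
print.root_position <- function(x, ...) {
  cat(sprintf("<root_position> edge to node %d, offset %.6g from parent\n",
              x$child, x$offset))
  invisible(x)
}

## Resolve a root_position against a tree; returns parent, child, edge
## length and an offset clamped into [0, e] (within float slack).
resolve_position <- function(tree, pos) {
  if (!inherits(pos, "root_position")) stop("`pos` must be a root_position")
  n <- length(tree$tip.label)
  N <- n + tree$Nnode
  v <- pos$child
  if (v < 1L || v > N) stop("position child node is not in the tree")
  k <- match(v, tree$edge[, 2])
  if (is.na(k)) stop("position child node has no parent edge (is it the root?)")
  u <- tree$edge[k, 1]
  ev <- tree$edge.length[k]
  x <- pos$offset
  tol <- 1e-9 * max(1, ev)
  if (x < -tol || x > ev + tol)
    stop(sprintf("offset %g outside [0, %g] on edge to node %d", x, ev, v))
  list(parent = u, child = v, elen = ev, offset = min(max(x, 0), ev))
}

#' Reroot a tree at an arbitrary point on an edge
#'
#' Inserts a new root vertex at the given point, splitting the host edge
#' into two pieces whose lengths sum to the original, and re-orients every
#' edge away from the new root.  When the point coincides with a node no
#' degree-2 vertex is created: the tree is rooted at that node (a leaf
#' endpoint is the one exception, where a root with a zero-length pendant
#' edge to the leaf is inserted instead).  If the input tree had a
#' bifurcating root that is not the new root, that old root is suppressed
#' and its two incident edges merged, so the result corresponds to a fresh
#' rooting of the underlying unrooted tree.  The total branch length is
#' always conserved.
#'
#' Internal node labels (e.g. support values) travel with their nodes and
#' are not re-mapped to the new bipartitions; interpret them with care
#' after rerooting.
#'
#' @param tree A `phylo` with branch lengths.
#' @param pos A [root_position()] on an edge of `tree`.
#' @return A rooted `phylo` over the same leaves.
#' @examples
#' tr <- read_newick(text = "(A:1,B:3,C:4);")[[1]]
#' rooted <- reroot_at(tr, root_position(match("C", tr$tip.label), 1))
#' tip_distances(rooted)
#' @export
reroot_at <- function(tree, pos) {
  rp <- resolve_position(tree, pos)
  n <- length(tree$tip.label)
  N <- n + tree$Nnode
  old_root <- n + 1L

  ea <- tree$edge[, 1]; eb <- tree$edge[, 2]; ew <- tree$edge.length
  u <- rp$parent; v <- rp$child; ev <- rp$elen; x <- rp$offset

  at_parent <- x == 0
  at_child <- x == ev && v > n   # collapse only onto internal nodes
  if (at_parent) {
    new_root <- u
  } else if (at_child) {
    new_root <- v
  } else {
    new_root <- N + 1L           # fresh vertex on the host edge
    k <- match(v, eb)
    ea <- ea[-k]; eb <- eb[-k]; ew <- ew[-k]
    ea <- c(ea, u, new_root); eb <- c(eb, new_root, v); ew <- c(ew, x, ev - x)
  }

  ## Suppress a bifurcating old root that is no longer the root: in the
  ## unrooted tree it is not a real vertex.
  if (old_root != new_root) {
    inc <- which(ea == old_root | eb == old_root)
    if (length(inc) == 2L) {
      nb <- ifelse(ea[inc] == old_root, eb[inc], ea[inc])
      wmerged <- sum(ew[inc])
      ea <- ea[-inc]; eb <- eb[-inc]; ew <- ew[-inc]
      ea <- c(ea, nb[1]); eb <- c(eb, nb[2]); ew <- c(ew, wmerged)
    }
  }

  ## Orient everything away from new_root by an iterative preorder DFS.
  fr <- c(ea, eb); to <- c(eb, ea); w2 <- c(ew, ew)
  adj <- split(seq_along(fr), fr)
  adj_names <- as.integer(names(adj))
  adj_idx <- integer(max(N + 1L, new_root))
  adj_idx[adj_names] <- seq_along(adj)

  n_edges <- length(ea)
  new_E <- matrix(0L, n_edges, 2)
  new_len <- numeric(n_edges)
  ## new internal ids assigned in preorder; tips keep their ids
  newid <- integer(max(N + 1L, new_root))
  next_int <- n + 1L
  has_nl <- !is.null(tree$node.label)
  old_label <- if (has_nl) c(rep(NA_character_, n), tree$node.label) else NULL
  new_nl <- character(0)

  stack_node <- integer(n_edges + 1L); stack_par <- integer(n_edges + 1L)
  stack_len <- numeric(n_edges + 1L)
  top <- 1L
  stack_node[1] <- new_root; stack_par[1] <- 0L
  row <- 0L
  while (top > 0L) {
    node <- stack_node[top]; par <- stack_par[top]; plen <- stack_len[top]
    top <- top - 1L
    if (node > n) {
      newid[node] <- next_int
      if (has_nl) {
        lab <- if (node <= N && !is.na(old_label[node])) old_label[node] else ""
        new_nl <- c(new_nl, lab)
      }
      next_int <- next_int + 1L
    } else newid[node] <- node
    if (par > 0L) {
      row <- row + 1L
      new_E[row, ] <- c(newid[par], newid[node])
      new_len[row] <- plen
    }
    ii <- adj[[adj_idx[node]]]
    ## push in reverse so the first-listed neighbor is visited first
    for (j in rev(ii)) {
      nb <- to[j]
      if (nb != par) {
        top <- top + 1L
        stack_node[top] <- nb; stack_par[top] <- node; stack_len[top] <- w2[j]
      }
    }
  }

  out <- list(edge = new_E, edge.length = new_len,
              tip.label = tree$tip.label, Nnode = next_int - 1L - n)
  if (has_nl) out$node.label <- new_nl
  class(out) <- "phylo"
  attr(out, "order") <- "cladewise"
  out
}

#' Root-to-tip distances, mean and variance
#'
#' `tip_distances()` returns the path length from a point on the tree
#' (default: its current root) to every leaf.  `root_to_tip_stats()`
#' additionally returns their mean and population variance
#' `var = (1/n) * sum((d_i - mean)^2)`, the quantity minimized by
#' [minvar_root()].
#'
#' @param tree A `phylo` with branch lengths.
#' @param pos Optional [root_position()]; if omitted, distances are taken
#'   from the tree's current root.
#' @return A named numeric vector of distances (in `tip.label` order), or
#'   for `root_to_tip_stats()` a list with `distances`, `mean`, `var`.
#' @export
tip_distances <- function(tree, pos = NULL) {
  if (!is.null(pos)) tree <- reroot_at(tree, pos)
  tt <- tree_tables(tree)
  d <- node_depths(tt)[seq_len(tt$n)]
  names(d) <- tree$tip.label
  d
}

#' @rdname tip_distances
#' @export
root_to_tip_stats <- function(tree, pos = NULL) {
  d <- tip_distances(tree, pos)
  list(distances = d, mean = mean(d), var = pop_var(d))
}
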