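# Internal traversal scaffolding shared by the rooting algorithms.
#
# tree_tables() flattens a phylo into postorder-indexed arrays so the
# dynamic programs can run as plain loops over edges: `E` is the edge
# matrix in postorder (children appear before their parents), so scanning
# rows forward is a post-order sweep and backward a pre-order sweep.
tree_tables <- function(tree) {
  tree <- stats::reorder(tree, "postorder")
  E <- tree$edge
  len <- tree$edge.length
  n <- length(tree$tip.label)
  N <- n + tree$Nnode
  parent <- integer(N)
  elen <- numeric(N)
  parent[E[, 2]] <- E[, 1]
  elen[E[, 2]] <- len
  root <- E[nrow(E), 1]
  list(tree = tree, E = E, len = len, n = n, N = N,
       parent = parent, elen = elen, root = root)
}

# Distance from the current root to every node (branch-length metric).
node_depths <- function(tt) {
  depth <- numeric(tt$N)
  for (k in rev(seq_len(nrow(tt$E)))) {
    depth[tt$E[k, 2]] <- depth[tt$E[k, 1]] + tt$len[k]
  }
  depth
}

# Number of edges from the current root to every node.
node_edge_depths <- function(tt) {
  depth <- integer(tt$N)
  for (k in rev(seq_len(nrow(tt$E)))) {
    depth[tt$E[k, 2]] <- depth[tt$E[k, 1]] + 1L
  }
  depth
}

# Leaf count below every node.
clade_sizes <- function(tt) {
  size <- numeric(tt$N)
  size[seq_len(tt$n)] <- 1
  for (k in seq_len(nrow(tt$E))) {
    size[tt$E[k, 1]] <- size[tt$E[k, 1]] + size[tt$E[k, 2]]
  }
  size
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Population variance (divide by n), the convention used throughout.
pop_var <- function(x) {
  m <- mean(x)
  mean((x - m)^2)
}
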