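## Locate the edge whose removal separates exactly `labels` from the rest.
## Returns NULL when no such edge exists.  `og_side` reports whether the
## child endpoint of that edge is on the outgroup side.
find_separating_edge <- function(tree, labels) {
  tt <- tree_tables(tree)
  n <- tt$n
  idx <- match(labels, tt$tree$tip.label)
  if (anyNA(idx))
    stop("outgroup label(s) not in tree: ",
         paste(labels[is.na(idx)], collapse = ", "))
  if (length(idx) >= n)
    stop("outgroup must be a proper subset of the leaves")
  og_n <- length(idx)
  in_og <- numeric(tt$N)
  in_og[idx] <- 1
  size <- numeric(tt$N); size[seq_len(n)] <- 1
  for (k in seq_len(nrow(tt$E))) {
    p <- tt$E[k, 1]; v <- tt$E[k, 2]
    size[p] <- size[p] + size[v]
    in_og[p] <- in_og[p] + in_og[v]
  }
  for (k in rev(seq_len(nrow(tt$E)))) {
    v <- tt$E[k, 2]
    if (in_og[v] == og_n && size[v] == og_n)
      return(list(child = v, elen = tt$len[k], og_side = "child", tt = tt))
    if (in_og[v] == 0 && size[v] == n - og_n)
      return(list(child = v, elen = tt$len[k], og_side = "parent", tt = tt))
  }
  NULL
}

#' Is a taxon set an outgroup of this tree?
#'
#' `TRUE` when some edge of the (unrooted) tree separates exactly the
#' given labels from all remaining leaves, i.e. the set is monophyletic
#' under some rooting.  A single leaf always qualifies (its pendant edge
#' separates it).  Useful for summarizing, over a collection of gene
#' trees, how often the designated species-tree outgroup actually sits
#' outside the ingroups in each gene tree.
#'
#' @param tree A `phylo`.
#' @param outgroup Character vector of leaf labels.
#' @return Logical scalar.
#' @export
is_gene_tree_outgroup <- function(tree, outgroup) {
  !is.null(find_separating_edge(tree, outgroup))
}

#' Outgroup (OG) rooting
#'
#' Roots the tree on the edge separating a designated outgroup taxon set
#' from the remaining taxa.  The rationale: an outgroup is known
#' a priori to branch off before the ingroups, so the root must lie on
#' the edge between the two.  The offset along that edge is topologically
#' irrelevant for triplet or branch-distance scoring; the symmetric
#' midpoint is the default.
#'
#' @param tree A `phylo` with branch lengths.
#' @param outgroup Character vector of leaf labels forming the outgroup;
#'   must be separable from the remaining leaves by a single edge, else
#'   an error names the offending labels.
#' @param og_offset Where to place the root on the separating edge:
#'   `"midpoint"` (default), `"ingroup-end"`, or `"outgroup-end"`.
#' @return An object of class `tree_rooting`: a list with `method`
#'   (`"OG"`), `position`, `variance` (root-to-tip variance at the chosen
#'   root, for reporting), and `tree`.
#' @examples
#' tr <- read_newick(text = "(A:1,B:1,(C:1,D:1):1);")[[1]]
#' rt <- outgroup_root(tr, c("C", "D"))
#' rt$position$offset   # 0.5: midpoint of the separating edge
#' @export
outgroup_root <- function(tree, outgroup,
                          og_offset = c("midpoint", "ingroup-end",
                                        "outgroup-end")) {
  og_offset <- match.arg(og_offset)
  sep <- find_separating_edge(tree, outgroup)
  if (is.null(sep))
    stop("outgroup is not separable by any single edge (non-monophyletic in every rooting): ",
         paste(outgroup, collapse = ", "))
  x <- switch(og_offset,
              "midpoint" = sep$elen / 2,
              ## offset is measured from the parent endpoint
              "ingroup-end" = if (sep$og_side == "child") 0 else sep$elen,
              "outgroup-end" = if (sep$og_side == "child") sep$elen else 0)
  pos <- root_position(sep$child, x)
  rooted <- reroot_at(sep$tt$tree, pos)
  structure(list(method = "OG", position = pos,
                 variance = pop_var(tip_distances(rooted)),
                 tree = rooted),
            class = "tree_rooting")
}
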