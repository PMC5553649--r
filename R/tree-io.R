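#' Read newick trees, one per line
#'
#' Reads a file (or literal text) holding one ';'-terminated newick string
#' per non-blank line and returns a list of validated `phylo` trees.  Every
#' branch of every tree must carry a finite, non-negative length: all the
#' rooting algorithms in this package operate on the branch-length metric,
#' so trees with missing lengths are rejected rather than silently padded.
#'
#' @param file Path to a newick file, or `NULL` when `text` is given.
#' @param text Optional character vector of newick strings (one tree per
#'   element), used instead of `file`.
#' @param clamp_negative If `TRUE`, negative branch lengths (as produced by
#'   some distance-based estimators) are replaced by 0 with a warning; the
#'   default is to reject them with an error naming the offending edge.
#' @return A list of `phylo` objects with class `multiPhylo`.
#' @examples
#' trees <- read_newick(text = "((A:1,B:1):1,C:2);")
#' trees[[1]]$tip.label
#' @seealso [write_newick()]
#' @export
read_newick <- function(file = NULL, text = NULL, clamp_negative = FALSE) {
  if (is.null(text)) {
    if (is.null(file)) stop("either `file` or `text` must be given")
    text <- readLines(file, warn = FALSE)
  }
  keep <- nzchar(trimws(text))
  lines <- text[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) stop("no newick strings found in input")
  trees <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    tr <- tryCatch(ape::read.tree(text = lines[[i]]),
                   error = function(e) NULL, warning = function(w) NULL)
    if (is.null(tr) || !inherits(tr, "phylo")) {
      stop(sprintf("malformed newick on line %d", lineno[i]))
    }
    trees[[i]] <- validate_tree(tr, line = lineno[i],
                                clamp_negative = clamp_negative)
  }
  class(trees) <- "multiPhylo"
  trees
}

#' Write trees as newick, one per line
#'
#' Branch lengths are printed with 15 significant digits so that a
#' read/write round trip preserves them to floating tolerance.
#'
#' @param trees A `phylo` object or a list of them.
#' @param file Output path, or `""` to return the newick strings invisibly
#'   and print them to stdout.
#' @return Invisibly, the character vector of newick strings.
#' @export
write_newick <- function(trees, file = "") {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (length(trees) == 0L) stop("no trees to write")
  out <- vapply(trees, function(tr) {
    if (is.null(tr$edge.length)) stop("tree has no branch lengths")
    ape::write.tree(tr, digits = 15)
  }, character(1))
  if (nzchar(file)) writeLines(out, file) else cat(out, sep = "\n")
  invisible(out)
}

## Structural validation shared by read_newick() and the generators.
validate_tree <- function(tree, line = NA_integer_, clamp_negative = FALSE) {
  where <- if (is.na(line)) "" else sprintf(" (line %d)", line)
  n <- length(tree$tip.label)
  if (n < 1L) stop("tree has no leaves", where)
  if (anyDuplicated(tree$tip.label))
    stop(sprintf("duplicate leaf labels%s: %s", where,
                 paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                       collapse = ", ")))
  if (any(!nzchar(tree$tip.label)))
    stop(sprintf("empty leaf label%s", where))
  if (is.null(tree$edge.length) || length(tree$edge.length) != nrow(tree$edge))
    stop(sprintf("missing branch lengths%s: every edge must have a length",
                 where))
  bad <- which(is.na(tree$edge.length) | !is.finite(tree$edge.length))
  if (length(bad))
    stop(sprintf("missing or non-finite branch length%s on edge to %s",
                 where, edge_name(tree, bad[1])))
  neg <- which(tree$edge.length < 0)
  if (length(neg)) {
    if (clamp_negative) {
      warning(sprintf("%d negative branch length(s)%s clamped to 0",
                      length(neg), where))
      tree$edge.length[neg] <- 0
    } else {
      stop(sprintf("negative branch length%s on edge to %s; use clamp_negative = TRUE to zero it",
                   where, edge_name(tree, neg[1])))
    }
  }
  tree
}

## Human-readable name for the child endpoint of edge row k.
edge_name <- function(tree, k) {
  v <- tree$edge[k, 2]
  n <- length(tree$tip.label)
  if (v <= n) sprintf("leaf '%s'", tree$tip.label[v])
  else sprintf("internal node %d", v)
}
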