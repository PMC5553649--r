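#' Generate a random ultrametric tree
#'
#' Substrate for the clock-deviation models: a rooted binary tree in
#' which every leaf is exactly `height` from the root (a strict molecular
#' clock).  Topology and node times come from either a Kingman
#' coalescent ([ape::rcoal()]) or a Yule pure-birth process
#' ([ape::rphylo()]), rescaled to the requested height.  Deterministic
#' given `seed`; the caller's RNG state is left untouched.
#'
#' @param n_leaves Number of leaves (>= 2).
#' @param height Root-to-tip height in branch-length units.
#' @param model `"coalescent"` (default) or `"yule"`.
#' @param seed Integer seed.
#' @return A rooted ultrametric `phylo` with tip labels `t1..tn`.
#' @export
generate_ultrametric <- function(n_leaves, height = 1,
                                 model = c("coalescent", "yule"),
                                 seed = 1L) {
  model <- match.arg(model)
  if (n_leaves < 2L) stop("need at least 2 leaves")
  if (height <= 0) stop("height must be positive")
  tr <- with_seed(seed, {
    if (model == "coalescent") ape::rcoal(n_leaves)
    else ape::rphylo(n_leaves, birth = 1, death = 0)
  })
  h <- max(tip_distances(tr))
  tr$edge.length <- tr$edge.length * (height / h)
  tr
}

#' Bounded random deviations from the clock
#'
#' Multiplies every branch of an ultrametric tree by an independent draw
#' from a mean-1 distribution supported on `[1 - epsilon, 1 + epsilon]`
#' (uniform by default).  Under this model the minimum-variance root is
#' guaranteed to fall on a root-adjacent edge for small enough `epsilon`,
#' and conditional on that, its signed distance from the true root has
#' expectation zero — the formal motivation for MV rooting.
#'
#' @param tree A rooted ultrametric `phylo`.
#' @param epsilon Half-width of the multiplier support, in `[0, 1)`.
#' @param seed Integer seed.
#' @param rdev Optional function `n -> n` multipliers; must have mean 1
#'   and support within `[1 - epsilon, 1 + epsilon]`.  Default: uniform.
#' @return The deviated `phylo` (same topology; the root node is the
#'   true root).
#' @export
apply_random_deviations <- function(tree, epsilon, seed = 1L, rdev = NULL) {
  if (epsilon < 0 || epsilon >= 1)
    stop("epsilon must be in [0, 1): the multiplier support must stay positive")
  m <- length(tree$edge.length)
  mult <- with_seed(seed, {
    if (is.null(rdev)) stats::runif(m, 1 - epsilon, 1 + epsilon)
    else rdev(m)
  })
  tree$edge.length <- tree$edge.length * mult
  tree
}

#' Gene-by-lineage and species-specific gamma rate heterogeneity
#'
#' Emulates the rate-heterogeneity structure of coalescent-based gene
#' tree simulations: for each tree ("gene"), a gamma shape `k` is drawn
#' as `exp(Normal(location, sigma))`; multipliers are then drawn from
#' `Gamma(shape = k, rate = k)`, which has mean exactly 1 for any `k`
#' (the distributions are mean-preserving, so only the shape varies).
#' Lower `location` gives smaller typical shapes, hence more dispersed
#' multipliers and stronger deviation from the clock; higher `location`
#' concentrates the multipliers around 1.
#'
#' @param trees A `phylo` or list of `phylo` (the gene trees).
#' @param location Log-normal location hyperparameter of the gamma shape
#'   (the "clock deviation parameter"; e.g. 0.15 = high, 1.5 = moderate,
#'   5 = low deviation).
#' @param sigma Log-normal scale hyperparameter (default 1).
#' @param per_gene_lineage One independent multiplier per branch per tree.
#' @param per_species One multiplier per leaf label, shared across all
#'   trees and applied to that species' pendant branch in each tree
#'   (trees must then share a label set).
#' @param seed Integer seed.
#' @return A list of deviated `phylo` objects.
#' @export
apply_gamma_rate_heterogeneity <- function(trees, location, sigma = 1,
                                           per_gene_lineage = TRUE,
                                           per_species = FALSE, seed = 1L) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  with_seed(seed, {
    species_mult <- NULL
    if (per_species) {
      labels <- sort(trees[[1]]$tip.label)
      for (tr in trees) {
        if (!setequal(labels, tr$tip.label))
          stop("per-species rates require a shared leaf label set")
      }
      k_s <- exp(stats::rnorm(1, location, sigma))
      species_mult <- stats::rgamma(length(labels), shape = k_s, rate = k_s)
      names(species_mult) <- labels
    }
    lapply(trees, function(tr) {
      if (per_gene_lineage) {
        k <- exp(stats::rnorm(1, location, sigma))
        tr$edge.length <- tr$edge.length *
          stats::rgamma(length(tr$edge.length), shape = k, rate = k)
      }
      if (per_species) {
        tip_edges <- match(seq_along(tr$tip.label), tr$edge[, 2])
        tr$edge.length[tip_edges] <- tr$edge.length[tip_edges] *
          species_mult[tr$tip.label]
      }
      tr
    })
  })
}

#' Attach an outgroup above an ingroup tree
#'
#' Adds a new root with two children: the ingroup tree below a stem of
#' length `rc_ratio * height(ingroup)` (the root-to-crown, R/C, ratio
#' controls how distant the outgroup is), and a single outgroup leaf
#' whose pendant length keeps the whole tree ultrametric.
#'
#' @param ingroup_tree A rooted ultrametric `phylo`.
#' @param rc_ratio Root-to-crown ratio (>= 0): stem length over ingroup
#'   height.
#' @param outgroup_label Label for the new leaf (must not collide).
#' @return A rooted ultrametric `phylo` with `n + 1` leaves.
#' @export
attach_outgroup <- function(ingroup_tree, rc_ratio, outgroup_label = "OUT") {
  if (rc_ratio < 0) stop("rc_ratio must be >= 0")
  if (outgroup_label %in% ingroup_tree$tip.label)
    stop("outgroup label collides with an ingroup leaf: ", outgroup_label)
  n <- length(ingroup_tree$tip.label)
  h <- max(tip_distances(ingroup_tree))
  ## renumber: tips 1..n keep ids, new tip n+1, new root n+2, old
  ## internals shift by 2
  shift <- function(id) ifelse(id > n, id + 2L, id)
  E <- cbind(shift(ingroup_tree$edge[, 1]), shift(ingroup_tree$edge[, 2]))
  E <- rbind(c(n + 2L, n + 3L),            # stem to old ingroup root
             c(n + 2L, n + 1L),            # pendant to outgroup leaf
             E)
  len <- c(rc_ratio * h, (1 + rc_ratio) * h, ingroup_tree$edge.length)
  out <- list(edge = E, edge.length = len,
              tip.label = c(ingroup_tree$tip.label, outgroup_label),
              Nnode = ingroup_tree$Nnode + 1L)
  if (!is.null(ingroup_tree$node.label))
    out$node.label <- c("", ingroup_tree$node.label)
  class(out) <- "phylo"
  stats::reorder(out, "cladewise")
}

#' Outgroup/ingroup discordance probability under the coalescent
#'
#' For an outgroup separated from the ingroups by an internal branch of
#' `branch_cu` coalescent units, under the idealization that only two
#' ingroup lineages remain to coalesce below the root, the probability
#' that a gene tree does *not* have the outgroup in the outgroup
#' position — discordance caused purely by incomplete lineage sorting —
#' is `(2/3) * exp(-branch_cu)`.
#'
#' @param branch_cu Branch length in coalescent units (>= 0).
#' @return Probability in `(0, 2/3]`.
#' @examples
#' outgroup_discordance_probability(2)   # ~0.09: 9% of gene trees
#' @export
outgroup_discordance_probability <- function(branch_cu) {
  if (any(branch_cu < 0)) stop("branch length must be >= 0")
  (2 / 3) * exp(-branch_cu)
}

#' Convert coalescent units to years
#'
#' One coalescent unit equals `2 * Ne` generations for a diploid
#' population, so `cu` units correspond to
#' `cu * 2 * diploid_Ne * generation_time_years` years.
#'
#' @param cu Branch length in coalescent units (>= 0).
#' @param diploid_Ne Diploid effective population size (> 0).
#' @param generation_time_years Generation time in years (> 0).
#' @return Time in years.
#' @examples
#' coalescent_units_to_years(2, 2e5, 10)   # 8,000,000 years
#' @export
coalescent_units_to_years <- function(cu, diploid_Ne, generation_time_years) {
  if (any(cu < 0)) stop("cu must be >= 0")
  if (diploid_Ne <= 0 || generation_time_years <= 0)
    stop("population size and generation time must be positive")
  cu * 2 * diploid_Ne * generation_time_years
}

#' Signed offset of the MV root from the true root of a deviated tree
#'
#' Runs [minvar_root()] on a clock-deviated tree whose root node is the
#' true root, and reports where the MV point landed relative to it.
#' When the MV point is on one of the (at most two) root-adjacent edges,
#' the signed offset is its distance from the root, positive toward the
#' root's first child and negative toward the second — the statistic
#' whose expectation is zero under the bounded random-deviations model.
#'
#' @param tree A rooted `phylo` whose root is the true root (e.g. output
#'   of [apply_random_deviations()]).
#' @return A list with `on_root_edge` (logical), `signed_offset`
#'   (`NA` unless on a root-adjacent edge), and `variance`.
#' @export
mv_offset_from_true_root <- function(tree) {
  rt <- minvar_root(tree)
  n <- length(tree$tip.label)
  root <- n + 1L
  kids <- tree$edge[tree$edge[, 1] == root, 2]
  v <- rt$position$child
  on_edge <- v %in% kids
  signed <- NA_real_
  if (on_edge) {
    side <- match(v, kids)
    signed <- if (side == 1L) rt$position$offset else -rt$position$offset
  }
  list(on_root_edge = on_edge, signed_offset = signed,
       variance = rt$variance)
}
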