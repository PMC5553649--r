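---
title: "Rooting trees by branch-length criteria: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rooting trees by branch-length criteria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treeroot)
```

## The problem

Trees inferred under time-reversible substitution models are unrooted,
yet most downstream uses — ancestral state reconstruction, dating,
summary species-tree methods that consume rooted gene trees — need a
root.  `treeroot` implements three rooting strategies on newick trees
with branch lengths, together with the metrics and synthetic data needed
to study their behavior.

A *rooting* of an unrooted tree picks a point $p$ on some edge
$(u, v)$: the edge is split at $p$ and all edges are directed away from
it.  Writing $d_i(p)$ for the path length from $p$ to leaf $i$
($i = 1, \dots, n$), the package works with

$$\mathrm{mean}(p) = \tfrac1n \sum_i d_i(p), \qquad
  \mathrm{var}(p) = \tfrac1n \sum_i (d_i(p) - \mathrm{mean}(p))^2 .$$

Note the *population* variance (divide by $n$): this is the quantity the
minimum-variance machinery is derived for, and `root_to_tip_stats()`
reports it.

## Minimum-variance (MV) rooting

`minvar_root()` finds the point minimizing $\mathrm{var}(p)$ over the
whole tree.  Under a strict molecular clock the true rooted tree is
ultrametric and the true root is the unique point of zero variance, so
minimizing the variance is a natural relaxation when rates deviate
randomly from a clock.  The contrast with midpoint rooting is the loss
function: MP minimizes the *maximum* root-to-tip distance, MV the
variance, which uses all leaves rather than the two extremes and is
correspondingly less sensitive to single long branches.

The algorithm orients the tree at an arbitrary starting root and runs
three linear-time traversals:

1. pre-order: distance from the starting root to every node, giving the
   starting variance;
2. post-order: for every node $u$, its clade size $|u|$ and
   $SI(u) = \sum_{i \in \mathrm{Cld}(u)} d_i(u)$, summed over all
   children (multifurcations are fully supported);
3. pre-order: $ST(u) = \sum_{i \in L} d_i(u)$ via
   $ST(v) = ST(p(v)) + (n - 2|v|)\,e_v$, and, on each edge, the
   closed-form variance quadratic.

For a point at offset $x$ from the parent $u$ on edge $(u,v)$,

$$\mathrm{var}(x) = (1-\beta^2)\,x^2 +
  \Big(\alpha - \tfrac{2\,ST(u)\,\beta}{n}\Big)\,x + \mathrm{var}(u),
  \qquad
  \alpha = \frac{2\,ST(u) - 4\,(SI(v) + |v|e_v)}{n}, \quad
  \beta = 1 - \frac{2|v|}{n}.$$

Since $|\beta| < 1$ on any proper edge, the leading coefficient is
positive and the constrained minimizer on $[0, e_v]$ is either the
parabola vertex $-b/2a$ (an interior *balance point*, where the mean
tip distance is equal on the two sides of the point) or an endpoint.
The global minimum over all edges — the starting root included — is
returned.  `edge_quadratics()` exposes the per-edge coefficients and
minimizers for inspection, and `brute_force_mv()` re-derives the
optimum from explicit path sums as an independent check.

### Correctness and numerical choices

* **Tie-breaking.**  Among candidates whose variances agree to within
  $10^{-12}\max(1, \mathrm{var})$, the first one encountered in the
  pre-order edge enumeration of the tree *as given* wins.  Exact ties
  are measure-zero for generic branch lengths; the choice only fixes
  which of several equivalent descriptions of the same point is
  reported.  The returned point itself is a property of the unrooted
  tree: the test suite verifies that re-orienting the input anywhere
  leaves the minimized variance and the sorted tip-distance vector
  unchanged.
* **Degenerate quadratics.**  $a = 0$ cannot occur on a proper edge,
  but collapsed or zero-length edges are guarded by falling back to
  endpoint comparison.
* **Zero-length edges** are permitted everywhere; a root position on
  one is pinned to offset 0.
* **Accumulation order.**  $SI$/$ST$ are accumulated in plain child
  order with double precision; at desk scale ($n \le 10^5$) this keeps
  the cross-checks against direct path sums well inside the $10^{-8}$
  tolerances used by the tests.  Compensated summation would only
  become worth considering far beyond that scale.
* **Variance clamp.**  The recursion can return values like
  $-10^{-17}$ for an exactly-zero variance; the reported variance is
  clamped at 0.
* **Two leaves.**  The general recursion already returns the path
  midpoint for $n = 2$; no special case is needed.

## Midpoint (MP) rooting

`midpoint_root()` roots at the middle of the longest leaf-to-leaf path
in two linear traversals: post-order maxima $MI(u)$ (deepest leaf below
$u$) and pre-order maxima $MO$ (deepest leaf through the parent).  On
the edge where $x^\* = (MI(v) - MO + e_v)/2$ lands in $[0, e_v]$, the
root is placed at offset $x^\*$ **from the parent endpoint** — the
orientation is fixed by requiring the root to be the diameter midpoint,
and is validated in the tests against a grid-search minimax oracle and
the exact identity $\max_i d_i = \mathrm{diameter}/2$.  When the
midpoint falls exactly on a node several edges qualify; the first in
pre-order is used (all describe the same point).  `tree_diameter()`
returns the exact diameter and a realizing leaf pair in linear time.

## Outgroup (OG) rooting

`outgroup_root()` places the root on the edge separating a user-supplied
taxon set from the rest, at the edge midpoint by default (`og_offset`
can pin it to either end; triplet and branch-distance metrics are
insensitive to the offset).  Multi-taxon outgroups are supported: the
set must be separable by a single edge in the unrooted tree, otherwise
the error names the labels.  `is_gene_tree_outgroup()` exposes the
separability test on its own, which is the natural summary of how often
a species-level outgroup is actually an outgroup in individual gene
trees.

## Rooting exactly at a node

`reroot_at()` never creates degree-2 vertices: an offset of 0 or $e_v$
roots at the existing node (avoiding unifurcations in the emitted
newick), and an old bifurcating root that is no longer the root is
suppressed and its two edges merged.  The single exception is a leaf
endpoint, where collapsing would make the leaf itself the root; a root
vertex with a zero-length pendant edge is inserted instead.  Internal
node labels travel with their nodes and are *not* re-mapped to the new
bipartitions — support values should be re-derived after rerooting if
they matter.

## Accuracy metrics

* `triplet_distance()` — the fraction of leaf triples whose rooted
  3-leaf topology in the reference is not reproduced by the estimate.
  Triples unresolved in the reference are excluded from the
  denominator; triples resolved in the reference but unresolved in the
  estimate count as mismatches.  The implementation enumerates all
  $\binom n3$ triples from an MRCA-depth table, an $O(n^3)$ strategy
  chosen deliberately: at evaluation scale ($n \le 100$ or so) it is
  fast enough, and simple enough to check against an independent
  pruning oracle, which the tests do exactly for $n \le 8$.
* `ideal_rooting()` — the best triplet distance achievable by rooting
  the estimate anywhere; it is zero precisely when the unrooted
  estimate is topologically correct, so `triplet - ideal` (the *delta
  triplet distance*) isolates rooting error from reconstruction error.
* `branch_distance()` — for roots placed on the true tree itself: 0
  when the estimated root shares the true root's host edge (for a
  bifurcating true root, its two incident edges count as one unrooted
  edge), otherwise 1 plus the number of complete edges strictly between
  the two points, normalized by the maximum root-to-leaf edge count
  measured from the true root.  The denominator is measured from the
  *true* root because the intended use is scoring rootings of true
  simulated gene trees, where that root is the reference.
* `rf_distance()` — normalized unrooted Robinson–Foulds distance,
  implemented from bipartition sets and cross-checked against
  `phangorn::RF.dist` in the tests.

`evaluate_rootings()` drives the above over aligned lists of reference
and estimate trees and returns one tidy row per tree and method.

## Synthetic clock-deviated trees

The generator exists to put the rooting methods in exactly the regime
their theory addresses, with every knob explicit:

* `generate_ultrametric()` — coalescent (`ape::rcoal`) or Yule
  (`ape::rphylo`) topologies rescaled to a chosen height (default 1, so
  deviations are read as relative rates).  All generators take an
  explicit seed, restore the caller's RNG state, and are byte-level
  reproducible.
* `apply_random_deviations()` — multiplies every branch by an i.i.d.
  draw from a mean-1 distribution on $[1-\epsilon, 1+\epsilon]$
  (uniform by default; any mean-1 bounded sampler can be plugged in).
  This is the bounded random-deviations clock model: for small
  $\epsilon$ the MV root provably stays on a root-adjacent edge, and
  conditional on that its signed offset from the true root has mean
  zero.  `mv_offset_from_true_root()` measures exactly that statistic,
  and the acceptance suite confirms both properties by Monte-Carlo
  (2000 replicates of 16-leaf trees at $\epsilon = 0.05$, a size/count
  combination chosen to keep the whole run in seconds while leaving the
  standard error well below any bias of practical size).
  `deviation_bound()` reports a sufficient $\epsilon$ threshold for the
  root-adjacency guarantee; its printed form follows one defensible
  grouping of a tersely typeset expression, so the tests rely on fixed
  small $\epsilon$ values rather than on the bound itself.
* `apply_gamma_rate_heterogeneity()` — the gene-by-lineage and
  species-specific rate-multiplier structure used in coalescent
  simulation studies: per tree, a gamma shape $k = \exp(N(\mu,
  \sigma))$ with $\sigma = 1$ by default, multipliers
  $\Gamma(k, \mathrm{rate} = k)$ so the mean is exactly 1 for every
  $k$.  The location $\mu$ is the single "clock deviation parameter":
  0.15, 1.5 and 5 reproduce high, moderate and low deviation regimes,
  an ordering the tests verify through the coefficient of variation of
  root-to-tip distances.
* `attach_outgroup()` — adds an outgroup as sister to the ingroups at a
  chosen root-to-crown (R/C) ratio, keeping the species tree
  ultrametric; `outgroup_discordance_probability()` gives the
  closed-form ILS probability $(2/3)e^{-t}$ that a gene tree mixes the
  outgroup into the ingroups across a separating branch of $t$
  coalescent units (under the idealization that only two lineages
  remain to coalesce below the root), and
  `coalescent_units_to_years()` converts $t$ to years via
  $2 N_e$ generations per unit.

**What the generator does not emulate.**  There is no sequence
evolution, no gene-tree estimation error, and no multispecies-coalescent
gene-tree sampling: trees deviate from the clock, never from the species
topology.  Passing tests therefore demonstrate the algorithms' behavior
under clock deviation — global optimality, unbiasedness around the true
root, the MV-versus-MP ordering — but say nothing about robustness to
topological gene-tree error, which in real pipelines is often the
dominant term.  The analytic discordance helper quantifies how often ILS
alone would displace an outgroup, precisely the effect the simulator
does not generate.

## Problem sizes and test design

The test suite regenerates all fixtures in code: 200 random trees of
3–12 leaves for the global-optimality check against `brute_force_mv()`
(grid plus exact interpolated parabola vertex per edge, all evaluated by
explicit path sums over `ape::dist.nodes`), balance-point and
invariance properties on dozens of re-orientations, and a scaling check
that times the MV scan on trees of $10^3$–$10^5$ leaves and requires an
$R^2 > 0.98$ linear fit.  These sizes were picked so the whole suite
runs in well under a minute while every property is exercised far from
its trivial cases.  The command-line front end (`exec/treeroot`, with
`reroot`, `evaluate` and `simulate` subcommands) is a thin wrapper over
the exported functions and is exercised both in-process and as an
installed script.

## Known limitations

* Support values are not re-oriented on rerooting.
* `triplet_distance()` is $O(n^3)$ by design; very large evaluation
  sets would want the sub-quadratic algorithms from the literature.
* Negative branch lengths are rejected (or zeroed with
  `clamp_negative`); the variance quadratic assumes a non-negative
  metric.
* The MV criterion is a geometric optimization, not a statistical
  minimum-variance estimator; no standard errors accompany the root
  placement.
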