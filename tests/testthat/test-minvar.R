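test_that("clade statistics match direct path-sum definitions", {
  tr <- read_newick(text = "((A:1,B:1):1,C:2);")[[1]]
  cs <- clade_stats(tr)
  n <- length(tr$tip.label)
  root <- n + 1L
  expect_equal(cs$size[root], 3)
  expect_equal(cs$SI[root], 6)               # d_A + d_B + d_C = 2+2+2
  expect_equal(cs$ST[root], cs$SI[root])     # root's clade is all leaves
  expect_true(all(cs$size[1:n] == 1))
  expect_true(all(cs$SI[1:n] == 0))

  ## random trees: ST(u) equals the direct sum of tip distances to u
  set.seed(31)
  for (i in 1:8) {
    tr <- rand_tree(sample(4:12, 1))
    cs <- clade_stats(tr)
    dn <- ape::dist.nodes(tr)
    n <- length(tr$tip.label)
    direct <- colSums(dn[1:n, , drop = FALSE])
    expect_equal(cs$ST, unname(direct[cs$node]), tolerance = 1e-9)
  }
})

test_that("the per-edge quadratic reproduces endpoint variances", {
  set.seed(32)
  for (i in 1:20) {
    tr <- rand_tree(10)
    q <- edge_quadratics(tr)
    for (k in sample(nrow(q), 4)) {
      row <- q[k, ]
      ## at x = 0 the quadratic is var(parent); at x = e_v it is var(child)
      v_par <- root_to_tip_stats(tr, root_position(row$child, 0))$var
      v_chl <- root_to_tip_stats(tr, root_position(row$child, row$elen))$var
      expect_equal(row$c, v_par, tolerance = 1e-8)
      expect_equal(row$a * row$elen^2 + row$b * row$elen + row$c, v_chl,
                   tolerance = 1e-8)
      expect_gte(row$a, 0)  # 1 - beta^2 with |beta| < 1 on proper edges
    }
  }
})

test_that("leaf edges have beta = 1 - 2/n", {
  set.seed(33)
  tr <- rand_tree(9)
  q <- edge_quadratics(tr)
  leaf_rows <- q$child <= length(tr$tip.label)
  expect_equal(q$beta[leaf_rows], rep(1 - 2 / 9, sum(leaf_rows)))
})

test_that("3-leaf star: per-edge balance points match the hand solution", {
  q <- edge_quadratics(star3())
  labelled <- merge(q, data.frame(child = 1:3, label = star3()$tip.label))
  byl <- split(labelled, labelled$label)
  ## edge toward C: 4 - x = ((1+x)+(3+x))/2  =>  x* = 1, var 2/3
  expect_equal(byl$C$x_star, 1, tolerance = 1e-12)
  expect_equal(byl$C$var_star, 2 / 3, tolerance = 1e-12)
  expect_true(byl$C$interior)
  ## edge toward B: 3 - x = 2.5 + x  =>  x* = 0.25, var 1.5
  expect_equal(byl$B$x_star, 0.25, tolerance = 1e-12)
  expect_equal(byl$B$var_star, 1.5, tolerance = 1e-12)
  ## edge toward A: interior solution -1.25 infeasible, endpoint x* = 0
  expect_equal(byl$A$x_star, 0)
  expect_false(byl$A$interior)
})

test_that("constrained quadratic minimization covers degenerate cases", {
  expect_equal(minimize_edge_quadratic(1, -2, 3, 5)$x, 1)     # vertex inside
  expect_equal(minimize_edge_quadratic(1, -20, 3, 5)$x, 5)    # vertex beyond
  expect_equal(minimize_edge_quadratic(1, 2, 3, 5)$x, 0)      # vertex before
  expect_equal(minimize_edge_quadratic(0, -1, 3, 5)$x, 5)     # linear, a = 0
  expect_equal(minimize_edge_quadratic(0, 1, 3, 5)$x, 0)
})

test_that("minvar_root equals brute-force grid search on random trees", {
  set.seed(34)
  for (i in 1:200) {
    tr <- rand_tree(sample(3:12, 1))
    fast <- minvar_root(tr)
    slow <- brute_force_mv(tr, grid_points_per_edge = 25)
    expect_equal(fast$variance, slow$variance, tolerance = 1e-6)
    ## the reported variance is realized at the reported position
    expect_equal(root_to_tip_stats(tr, fast$position)$var, fast$variance,
                 tolerance = 1e-8)
  }
})

test_that("interior local minima are balance points", {
  set.seed(35)
  checked <- 0L
  for (i in 1:30) {
    tr <- rand_tree(sample(4:12, 1))
    q <- edge_quadratics(tr)
    dn <- ape::dist.nodes(tr)
    n <- length(tr$tip.label)
    for (k in which(q$interior)) {
      u <- q$parent[k]; v <- q$child[k]; ev <- q$elen[k]; x <- q$x_star[k]
      under <- tips_under(dn, n, u, v, ev)
      d <- point_tip_dists(dn, n, u, v, ev, x, under)
      ## equal mean tip distance on the two sides of the point
      expect_equal(mean(d[under]), mean(d[!under]), tolerance = 1e-8)
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 30)
})

test_that("every tree yields at least one local minimum candidate", {
  set.seed(36)
  for (i in 1:20) {
    tr <- rand_tree(sample(2:10, 1))
    rt <- minvar_root(tr)
    expect_true(is.finite(rt$variance))
    expect_gte(rt$variance, 0)
  }
})

test_that("the minimum-variance point is invariant to the input rooting", {
  set.seed(37)
  for (i in 1:50) {
    tr <- rand_tree(sample(4:12, 1))
    v1 <- minvar_root(tr)
    k <- sample(nrow(tr$edge), 1)
    alt <- reroot_at(tr, root_position(tr$edge[k, 2],
                                       stats::runif(1) * tr$edge.length[k]))
    v2 <- minvar_root(alt)
    expect_equal(v1$variance, v2$variance, tolerance = 1e-9)
    ## same point of the unrooted tree: identical sorted tip distances
    expect_equal(sort(unname(tip_distances(v1$tree))),
                 sort(unname(tip_distances(v2$tree))), tolerance = 1e-8)
  }
})

test_that("ultrametric trees are rooted at their true root with variance 0", {
  for (s in 1:5) {
    t0 <- generate_ultrametric(12, height = 1.5, seed = s)
    ## scramble the orientation, then recover
    k <- 7L
    scr <- reroot_at(t0, root_position(t0$edge[k, 2], 0.3 * t0$edge.length[k]))
    rt <- minvar_root(scr)
    expect_lt(rt$variance, 1e-15)
    d <- tip_distances(rt$tree)
    expect_lt(diff(range(d)), 1e-8)
    expect_equal(unname(d[1]), 1.5, tolerance = 1e-8)
  }
})

test_that("two-leaf trees are rooted at the path midpoint", {
  tr <- read_newick(text = "(A:1,B:5);")[[1]]
  rt <- minvar_root(tr)
  expect_equal(unname(tip_distances(rt$tree)[c("A", "B")]), c(3, 3))
  expect_equal(rt$variance, 0)
  expect_error(minvar_root(read_newick(text = "(A:1);")[[1]]), "2 leaves")
})

test_that("the clock-deviation bound helper is positive and scale-aware", {
  t0 <- generate_ultrametric(16, height = 1, seed = 5)
  b <- deviation_bound(t0)
  expect_true(is.finite(b) && b > 0)
  ## doubling all branch lengths leaves the (scale-free) bound unchanged
  t2 <- t0; t2$edge.length <- 2 * t2$edge.length
  expect_equal(deviation_bound(t2), b, tolerance = 1e-12)
})
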