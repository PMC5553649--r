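test_that("ultrametric generation is ultrametric, scaled and seed-deterministic", {
  for (model in c("coalescent", "yule")) {
    t0 <- generate_ultrametric(12, height = 2.5, model = model, seed = 7)
    d <- tip_distances(t0)
    expect_lt(diff(range(d)), 1e-9)
    expect_equal(unname(d[1]), 2.5, tolerance = 1e-9)
    again <- generate_ultrametric(12, height = 2.5, model = model, seed = 7)
    expect_identical(write_newick(t0, tempfile()), write_newick(again, tempfile()))
    other <- generate_ultrametric(12, height = 2.5, model = model, seed = 8)
    expect_false(identical(write_newick(t0, tempfile()),
                           write_newick(other, tempfile())))
  }
  t2 <- generate_ultrametric(2, height = 3, seed = 1)
  expect_equal(unname(t2$edge.length), c(3, 3))
  expect_error(generate_ultrametric(1, seed = 1), "2 leaves")
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(99); a <- stats::runif(1)
  set.seed(99); invisible(generate_ultrametric(8, seed = 3))
  invisible(apply_random_deviations(generate_ultrametric(8, seed = 3), 0.1,
                                    seed = 4))
  b <- stats::runif(1)
  expect_identical(a, b)
})

test_that("random deviations are bounded, mean-preserving and epsilon-0 is the identity", {
  t0 <- generate_ultrametric(10, seed = 2)
  same <- apply_random_deviations(t0, 0, seed = 5)
  expect_equal(same$edge.length, t0$edge.length)
  expect_error(apply_random_deviations(t0, 1), "epsilon")
  ## support bounds and mean 1 within 3 SE over ~10^4 multipliers
  ratios <- unlist(lapply(1:600, function(s) {
    dv <- apply_random_deviations(t0, 0.3, seed = s)
    dv$edge.length / t0$edge.length
  }))
  expect_true(all(ratios >= 0.7 - 1e-12 & ratios <= 1.3 + 1e-12))
  se <- stats::sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - 1), 3 * se)
})

test_that("small deviations keep the MV root on a root-adjacent edge", {
  t0 <- generate_ultrametric(16, seed = 11)
  landed <- vapply(1:300, function(s) {
    dv <- apply_random_deviations(t0, 0.01, seed = s)
    mv_offset_from_true_root(dv)$on_root_edge
  }, logical(1))
  expect_gte(mean(landed), 0.99)
})

test_that("gamma rate heterogeneity is mean-preserving and ordered by the deviation parameter", {
  t0 <- generate_ultrametric(12, seed = 21)
  ## shape -> infinity: multipliers -> 1, trees stay near-ultrametric
  near <- apply_gamma_rate_heterogeneity(t0, location = 12, sigma = 0.01,
                                         seed = 1)[[1]]
  expect_lt(root_to_tip_stats(near)$var, 1e-4)
  ## mean multiplier ~ 1 within 3 SE over many branches
  trees <- apply_gamma_rate_heterogeneity(rep(list(t0), 500), location = 1.5,
                                          seed = 2)
  ratios <- unlist(lapply(trees, function(tr) tr$edge.length / t0$edge.length))
  se <- stats::sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - 1), 3 * se)
  ## coefficient of variation of root-to-tip distances grows as the
  ## deviation parameter drops
  cv_at <- function(loc) {
    trees <- apply_gamma_rate_heterogeneity(rep(list(t0), 100), location = loc,
                                            seed = 3)
    stats::median(vapply(trees, function(tr) {
      st <- root_to_tip_stats(tr)
      sqrt(st$var) / st$mean
    }, numeric(1)))
  }
  cvs <- vapply(c(0.15, 1.5, 5), cv_at, numeric(1))
  expect_true(cvs[1] > cvs[2] && cvs[2] > cvs[3])
})

test_that("per-species rates rescale exactly the pendant branches, shared across genes", {
  t0 <- generate_ultrametric(8, seed = 31)
  trees <- apply_gamma_rate_heterogeneity(list(t0, t0), location = 0.5,
                                          per_gene_lineage = FALSE,
                                          per_species = TRUE, seed = 4)
  for (tr in trees) {
    tip_edges <- match(seq_along(tr$tip.label), tr$edge[, 2])
    expect_equal(tr$edge.length[-tip_edges], t0$edge.length[-tip_edges])
  }
  m1 <- trees[[1]]$edge.length / t0$edge.length
  m2 <- trees[[2]]$edge.length / t0$edge.length
  expect_equal(m1, m2)  # same species multipliers in both genes
})

test_that("outgroup attachment respects the root-to-crown ratio and stays ultrametric", {
  t0 <- generate_ultrametric(6, height = 1, seed = 41)
  full <- attach_outgroup(t0, rc_ratio = 1, outgroup_label = "OG1")
  d <- tip_distances(full)
  expect_lt(diff(range(d)), 1e-9)
  expect_equal(unname(d[["OG1"]]), 2, tolerance = 1e-9)   # pendant (1+R/C)*h
  og_edge <- full$edge.length[full$edge[, 2] == match("OG1", full$tip.label)]
  expect_equal(og_edge, 2, tolerance = 1e-9)
  expect_true(is_gene_tree_outgroup(full, "OG1"))
  ## R/C = 0: the stem vanishes and the root sits at the ingroup crown
  flat <- attach_outgroup(t0, rc_ratio = 0)
  stem <- flat$edge.length[flat$edge[, 2] ==
                             length(flat$tip.label) + 2L]
  expect_equal(stem, 0)
  expect_error(attach_outgroup(t0, 1, t0$tip.label[1]), "collides")
})

test_that("coalescent discordance and unit-conversion arithmetic", {
  expect_equal(outgroup_discordance_probability(0), 2 / 3)
  expect_equal(outgroup_discordance_probability(2), (2 / 3) * exp(-2))
  expect_equal(round(100 * outgroup_discordance_probability(2)), 9)
  expect_lt(outgroup_discordance_probability(50), 1e-20)
  expect_error(outgroup_discordance_probability(-1), ">= 0")

  expect_equal(coalescent_units_to_years(2, 2e5, 10), 8e6)
  expect_equal(coalescent_units_to_years(0, 2e5, 10), 0)
  ## linear in each argument
  expect_equal(coalescent_units_to_years(4, 2e5, 10),
               2 * coalescent_units_to_years(2, 2e5, 10))
  expect_equal(coalescent_units_to_years(2, 4e5, 10),
               2 * coalescent_units_to_years(2, 2e5, 10))
  expect_error(coalescent_units_to_years(1, 0, 10), "positive")
})
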