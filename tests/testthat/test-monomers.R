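test_that("threshold schedule spans [min, 1) with the given step", {
  s <- threshold_schedule()
  expect_equal(s[1], 0.94)
  expect_equal(s[2] - s[1], 0.005)
  expect_true(all(diff(s) > 0) && all(s < 1) && max(s) + 0.005 >= 1)
  expect_error(threshold_schedule(1.2), "0, 1")
  expect_error(threshold_schedule(0.94, 0), "positive")
})

test_that("block graph applies the strict-inequality edge rule", {
  S <- rbind(c(1, 0.97, 0.5, 0.5), c(0.97, 1, 0.5, 0.5),
             c(0.5, 0.5, 1, 0.97), c(0.5, 0.5, 0.97, 1))
  g <- build_block_graph(S, 0.94)
  comp <- igraph::components(g)
  expect_equal(comp$no, 2)
  expect_equal(igraph::ecount(build_block_graph(S, 0.98)), 0)
  expect_equal(igraph::ecount(build_block_graph(S, 0)), 6)
  # edge requires similarity strictly greater than the threshold
  expect_equal(igraph::ecount(build_block_graph(S, 0.97)), 0)
})

test_that("Louvain communities resolve cliques and isolated nodes", {
  S <- rbind(c(1, 0.97, 0.5, 0.5), c(0.97, 1, 0.5, 0.5),
             c(0.5, 0.5, 1, 0.97), c(0.5, 0.5, 0.97, 1))
  asg <- detect_monomers(build_block_graph(S, 0.94), seed = 1)
  expect_identical(asg$monomer_count, 2L)
  expect_identical(asg$community_of, c(1L, 1L, 2L, 2L))

  edgeless <- detect_monomers(build_block_graph(S, 0.98), seed = 1)
  expect_identical(edgeless$community_of, 1:4)

  complete <- detect_monomers(build_block_graph(S, 0.3), seed = 1)
  expect_identical(complete$monomer_count, 1L)
})

test_that("monomer sequence rewrites blocks through the member map", {
  m <- merge_identical(c("AAAA", "AAAA", "CCCC", "AAAA"))
  asg <- detect_monomers(build_block_graph(m, 0.94), m, seed = 1)
  expect_identical(to_monomer_sequence(m, asg), c(1L, 1L, 2L, 1L))
  single <- merge_identical("ACGT")
  asg1 <- detect_monomers(build_block_graph(single, 0.94), single, seed = 1)
  expect_identical(to_monomer_sequence(single, asg1), 1L)
})

test_that("zero HOR divergence recovers the five simulated monomers exactly", {
  ds <- simulate_hor_array(120, 0.2, 0, mode = "canonical", seed = 5)
  blocks <- decompose_monomers(ds$dna, ds$raw_template)
  merged <- merge_identical(blocks)
  asg <- detect_monomers(build_block_graph(merged, 0.94), merged, seed = 5)
  expect_identical(asg$monomer_count, 5L)
  mono <- to_monomer_sequence(merged, asg)
  # periodic ground truth up to an ID bijection; first-occurrence numbering
  # makes the bijection the identity here
  expect_identical(mono, rep(1:5, 40))
})

test_that("sweeps are reproducible and coarsen monotonically on nested similarities", {
  # three-level ultrametric toy matrix: within-group 0.99, sister groups
  # 0.96, across families 0.90
  S <- matrix(0.90, 8, 8)
  for (fam in list(1:4, 5:8)) S[fam, fam] <- 0.96
  for (grp in list(1:2, 3:4, 5:6, 7:8)) S[grp, grp] <- 0.99
  diag(S) <- 1
  counts <- vapply(c(0.85, 0.93, 0.975), function(t)
    detect_monomers(build_block_graph(S, t), seed = 1)$monomer_count,
    integer(1))
  expect_identical(counts, c(1L, 2L, 4L))
  expect_true(all(diff(counts) >= 0))

  m <- merge_identical(c("AAAA", "AAAA", "CCCC", "AAAA", "CCCC"))
  s1 <- sweep_thresholds(m, seed = 9)
  s2 <- sweep_thresholds(m, seed = 9)
  expect_identical(s1, s2)
  # fully identical blocks collapse to one monomer at every threshold
  ident <- merge_identical(rep("ACGTACGT", 6))
  sw <- sweep_thresholds(ident, seed = 1)
  expect_true(all(vapply(sw, function(r) r$assignment$monomer_count,
                         integer(1)) == 1L))
})
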