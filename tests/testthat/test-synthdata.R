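test_that("species-tree simulation is seeded and has coalescent heights", {
  u1 <- sim_species_tree(6, seed = 3)
  u2 <- sim_species_tree(6, seed = 3)
  expect_identical(u1$splits, u2$splits)
  expect_equal(u1$lengths, u2$lengths)
  set.seed(9)
  hts <- replicate(400, {
    u <- sim_species_tree(6)
    max(ape::node.depth.edgelength(attr(u, "phylo")))
  })
  # expected height of the Kingman coalescent with 7 tips
  expect_equal(mean(hts), sum(2 / ((2:7) * (1:6))), tolerance = 0.12)
})

test_that("the three rooted shapes on four tips are equally likely", {
  set.seed(10)
  cls <- replicate(900, {
    u <- sim_species_tree(3)
    u$splits[which.min(vapply(u$splits, bhvpca:::mask_size, integer(1)))]
  })
  counts <- table(cls)
  expect_equal(length(counts), 3L)
  expect_gt(stats::chisq.test(counts)$p.value, 1e-4)
})

test_that("gene trees track the species tree when branches are long", {
  u <- sim_species_tree(5, seed = 8)
  phy <- attr(u, "phylo")
  phy$edge.length <- phy$edge.length * 500
  g <- sim_gene_trees(phy, 60, seed = 9)
  conc <- mean(vapply(g, function(t) topology_key(t) == topology_key(u),
                      logical(1)))
  expect_gt(conc, 0.95)
  for (t in g[1:5]) {
    expect_true(fully_resolved(t))
    expect_true(all(t$lengths > 0))
  }
})

test_that("near-zero species branches give unconstrained coalescent shapes", {
  u <- sim_species_tree(3, seed = 11)
  phy <- attr(u, "phylo")
  phy$edge.length <- phy$edge.length * 1e-6
  set.seed(12)
  g <- sim_gene_trees(phy, 900)
  cls <- vapply(g, function(t) {
    t$splits[which.min(vapply(t$splits, bhvpca:::mask_size, integer(1)))]
  }, integer(1))
  expect_gt(stats::chisq.test(table(cls))$p.value, 1e-4)
})

test_that("gene-tree simulation is reproducible under a seed", {
  u <- sim_species_tree(6, seed = 2)
  g1 <- sim_gene_trees(u, 2, seed = 5)
  g2 <- sim_gene_trees(u, 2, seed = 5)
  expect_equal(g1[[1]]$lengths, g2[[1]]$lengths)
  expect_identical(g1[[2]]$splits, g2[[2]]$splits)
})

test_that("gamma-edge trees have the configured mean length", {
  set.seed(13)
  lens <- unlist(lapply(1:300, function(i) random_tree_gamma(6)$lengths))
  expect_equal(mean(lens), 0.1, tolerance = 0.05)  # shape/rate = 2/20
  expect_true(all(lens > 0))
  t1 <- random_tree_gamma(6, seed = 4)
  t2 <- random_tree_gamma(6, seed = 4)
  expect_equal(t1$lengths, t2$lengths)
})

test_that("NNI is involutive and the neighbourhood has size 2 x internal", {
  set.seed(14)
  x <- random_tree_gamma(8)
  nb <- all_nni(x)
  expect_equal(length(nb), 2L * length(x$splits))
  expect_equal(length(unique(vapply(nb, topology_key, character(1)))),
               length(nb))
  for (t in nb) expect_true(validate_topology_tree(t))
  # applying the interchange across the new edge with the right choice
  # restores the original topology
  q <- x$splits[3]
  t1 <- nni(x, q, 1, as_mask = TRUE)
  newq <- setdiff(t1$splits, x$splits)
  back <- c(topology_key(nni(t1, newq, 1, as_mask = TRUE)),
            topology_key(nni(t1, newq, 2, as_mask = TRUE)))
  expect_true(topology_key(x) %in% back)
})

test_that("every NNI is reachable by some SPR", {
  set.seed(15)
  for (r in 1:3) {
    y <- random_tree_gamma(5)
    nn <- vapply(all_nni(y), topology_key, character(1))
    sk <- all_spr_keys(y)
    expect_true(all(nn %in% sk))
  }
})

test_that("SPR preserves validity and moves lengths as documented", {
  set.seed(16)
  for (r in 1:20) {
    x <- random_tree_gamma(7)
    y <- rspr(x, 1)
    expect_true(validate_topology_tree(y))
    expect_equal(length(y$splits), length(x$splits))
    # total internal length is conserved (the destroyed edge's length
    # moves onto the created edge)
    expect_equal(sum(y$lengths), sum(x$lengths), tolerance = 1e-12)
  }
  expect_error(spr(random_tree_gamma(7, seed = 1), c(2, 3, 9), c(4)),
               "1..N")
})

test_that("random walks stay valid, are seeded, and scale with steps", {
  set.seed(17)
  x <- random_tree_gamma(8)
  expect_identical(random_walk_tree(x, 5, 0), x)
  w1 <- random_walk_tree(x, 5, 0.02, seed = 3)
  w2 <- random_walk_tree(x, 5, 0.02, seed = 3)
  expect_identical(w1$splits, w2$splits)
  expect_equal(w1$lengths, w2$lengths)
  expect_true(validate_topology_tree(w1))
  # mean squared displacement grows roughly linearly while walks stay
  # within one orthant (tiny steps)
  set.seed(18)
  d1 <- replicate(120, bhv_distance(x, random_walk_tree(x, 1, 0.002))^2)
  d4 <- replicate(120, bhv_distance(x, random_walk_tree(x, 4, 0.002))^2)
  expect_gt(mean(d4) / mean(d1), 2.5)
  expect_lt(mean(d4) / mean(d1), 6)
})

test_that("Dirichlet(4,4,4) draws avoid the simplex corners", {
  set.seed(19)
  P <- rdirichlet(4000, c(4, 4, 4))
  expect_equal(rowSums(P), rep(1, 4000), tolerance = 1e-12)
  expect_gt(stats::quantile(P[, 1], 0.05), 0.05)
})

test_that("surface datasets sit on the locus when the walk is off", {
  ds0 <- make_surface_dataset(n = 6, walk_steps = 0, walk_step_size = 0,
                              seed = 30)
  d2 <- sum(vapply(ds0$Z, function(z) {
    project_geometric(z, ds0$W, seed = 1, eps = 1e-3)$distance
  }, numeric(1))^2)
  expect_lt(d2, 1e-4)
})

test_that("larger walk steps produce more dispersed datasets", {
  dl <- make_surface_dataset(n = 10, dispersion = "low", seed = 30)
  dh <- make_surface_dataset(n = 10, dispersion = "high", seed = 30)
  d2 <- function(ds) sum(vapply(ds$Z, function(z) {
    project_geometric(z, ds$W, seed = 1, eps = 1e-3)$distance
  }, numeric(1))^2)
  expect_gt(d2(dh), d2(dl))
})

test_that("the validation harness reports coherent summaries", {
  h <- validation_harness(3, seed = 42)
  expect_equal(h$reps, 3)
  expect_equal(nrow(h$detail), 3)
  expect_true(h$pass_fraction >= 0 && h$pass_fraction <= 1)
  expect_true(all(h$detail$d_geometric >= 0))
  if (h$n_fail > 0) {
    expect_true(is.finite(h$mean_disagreement_pct))
    expect_gt(h$mean_disagreement_pct, 0)
  } else {
    expect_true(is.na(h$mean_disagreement_pct))
  }
  h2 <- validation_harness(3, seed = 42)
  expect_equal(h$detail$d_geometric, h2$detail$d_geometric)
})
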