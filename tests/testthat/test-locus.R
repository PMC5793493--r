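v5 <- fixture_t5()

test_that("the sampled locus contains vertices and vertex-pair geodesics", {
  ls <- locus_sample(v5, resolution = 4, eps = 1e-4, max_iter = 2e6)
  expect_equal(nrow(ls$p), 15L)
  corners <- which(apply(ls$p, 1, max) == 1)
  for (i in corners) {
    vi <- which(ls$p[i, ] == 1)
    expect_lt(bhv_distance(ls$trees[[i]], v5[[vi]]), 1e-9)
  }
  # simplex-edge points lie on the corresponding geodesic
  edges <- which(apply(ls$p, 1, function(p) sum(p == 0) == 1 & max(p) < 1))
  for (i in edges) {
    pair <- which(ls$p[i, ] > 0)
    g <- bhv_geodesic(v5[[pair[1]]], v5[[pair[2]]])
    resid <- bhv_distance(v5[[pair[1]]], ls$trees[[i]]) +
      bhv_distance(ls$trees[[i]], v5[[pair[2]]]) - g$length
    expect_lt(abs(resid), 1e-3)
  }
})

test_that("the locus of a subset is contained in the full locus", {
  set.seed(41)
  V <- lapply(1:3, function(i) random_tree_gamma(8))
  g <- bhv_geodesic(V[[1]], V[[2]])   # Pi({v0, v1})
  for (lam in c(0.25, 0.5, 0.75)) {
    pt <- geodesic_point(g, lam)
    pr <- project_geometric(pt, V, seed = 5, eps = 1e-4)
    expect_lt(pr$distance, 5e-3)
  }
})

test_that("projection of a vertex or surface point is exact", {
  set.seed(42)
  V <- lapply(1:3, function(i) random_tree_gamma(7))
  pr <- project_geometric(V[[2]], V, seed = 3, eps = 1e-5)
  expect_lt(pr$distance, 5e-3)
  expect_gt(pr$weights[2], 0.95)
  # exhaustive search recovers a lattice point placed on the surface
  pstar <- c(0.5, 0.25, 0.25)
  z <- frechet_mean(V, pstar, eps = 1e-5)$mean
  ex <- project_exhaustive(z, V, resolution = 8, eps = 1e-4)
  expect_lt(ex$distance, 1e-3)
  expect_equal(unname(ex$weights), pstar, tolerance = 1e-9)
})

test_that("geometric projection is idempotent within tolerance", {
  set.seed(43)
  V <- lapply(1:3, function(i) random_tree_gamma(7))
  z <- random_tree_gamma(7)
  pr <- project_geometric(z, V, seed = 1, eps = 1e-4)
  pr2 <- project_geometric(pr$projected, V, seed = 2, eps = 1e-4)
  expect_lt(pr2$distance, 2e-3)
})

test_that("multi-restart projection never does worse than single start", {
  set.seed(44)
  V <- lapply(1:3, function(i) random_tree_gamma(7))
  z <- random_tree_gamma(7)
  d1 <- project_geometric(z, V, seed = 11, eps = 1e-3)$distance
  d5 <- project_geometric(z, V, seed = 11, eps = 1e-3, restarts = 5)$distance
  expect_lte(d5, d1 + 1e-12)
})

test_that("sums of squared projection distances behave", {
  set.seed(45)
  V <- lapply(1:3, function(i) random_tree_gamma(7))
  d2 <- sum_squared_projected(V, V, eps = 1e-4, seed = 6)
  expect_lt(as.numeric(d2), 1e-3)
  expect_length(attr(d2, "projections"), 3L)
})

test_that("r-squared modes split residual and dispersion as documented", {
  set.seed(46)
  V <- lapply(1:3, function(i) random_tree_gamma(7))
  # data on the surface, spread out: explained 1, literal 0
  Z <- lapply(list(c(0.8, 0.1, 0.1), c(0.1, 0.8, 0.1), c(0.2, 0.3, 0.5)),
              function(p) frechet_mean(V, p, eps = 1e-5)$mean)
  pr <- lapply(Z, project_geometric, V = V, eps = 1e-5)
  r2e <- r_squared(Z, V, projections = pr)
  r2l <- r_squared(Z, V, mode = "literal", projections = pr)
  expect_gt(r2e, 0.999)
  expect_lt(r2l, 0.001)
  # all data projecting to one point: degenerate, explained mode 0
  Z1 <- list(V[[1]], V[[1]])
  pr0 <- project_geometric(V[[1]], V, eps = 1e-4, seed = 2)
  pr1 <- list(pr0, pr0)
  r2d <- r_squared(Z1, V, projections = pr1)
  expect_equal(as.numeric(r2d), 0)
  expect_true(isTRUE(attr(r2d, "degenerate")))
})

test_that("the simplex topology map shades orthants", {
  # one-orthant configuration: a single topology everywhere
  set.seed(47)
  base <- random_tree_gamma(6)
  V1 <- lapply(1:3, function(i) {
    t <- base; t$lengths <- rgamma(length(t$lengths), 2, 8); t
  })
  mp <- simplex_topology_map(V1, resolution = 4, eps = 1e-3)
  expect_equal(length(unique(mp$topology)), 1L)
  # the T5 example: at least the three vertex topologies appear
  mp5 <- simplex_topology_map(v5, resolution = 6, eps = 1e-3)
  expect_gte(length(unique(mp5$topology)), 3L)
  for (i in 1:3) {
    p <- rep(0, 3); p[i] <- 1
    corner <- which(apply(mp5[, 1:3], 1, function(q) all(q == p)))
    expect_equal(mp5$topology[corner], topology_key(v5[[i]]))
  }
})
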