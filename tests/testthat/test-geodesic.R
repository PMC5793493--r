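v5 <- fixture_t5()

test_that("fixture geodesics have the published lengths and supports", {
  # kinked cone path through the star point of the (xi1, xi2) plane
  g12 <- bhv_geodesic(v5$v1, v5$v2)
  expect_equal(g12$length, 2 * sqrt(5), tolerance = 1e-12)
  expect_equal(length(g12$support$A), 1L)
  expect_equal(length(g12$support$A[[1]]$mask), 2L)
  expect_equal(length(g12$support$B[[1]]$mask), 2L)
  expect_false(is_simple(g12))
  # straight segments to v0
  g01 <- bhv_geodesic(v5$v0, v5$v1)
  expect_equal(g01$length, sqrt(10), tolerance = 1e-12)
  expect_true(is_simple(g01))
  g02 <- bhv_geodesic(v5$v0, v5$v2)
  expect_equal(g02$length, sqrt(10), tolerance = 1e-12)
})

test_that("identical and same-orthant pairs reduce to the Euclidean case", {
  g <- bhv_geodesic(v5$v0, v5$v0)
  expect_equal(length(g$support$A), 0L)
  expect_equal(g$length, 0)
  w <- v5$v0; w$lengths <- c(2, 0.5, 1)
  expect_equal(bhv_distance(v5$v0, w),
               sqrt(sum((v5$v0$lengths - w$lengths)^2)), tolerance = 1e-12)
  expect_error(bhv_distance(v5$v0, random_tree_gamma(6, seed = 1)),
               "leaf sets")
})

test_that("points along geodesics follow the support schedule", {
  g12 <- bhv_geodesic(v5$v1, v5$v2)
  expect_equal(t5_coords(geodesic_point(g12, 0)), t5_coords(v5$v1))
  expect_equal(t5_coords(geodesic_point(g12, 1)), t5_coords(v5$v2))
  # the midpoint is the cone point (0, 0, 1)
  expect_equal(t5_coords(geodesic_point(g12, 0.5)), c(0, 0, 1),
               tolerance = 1e-12)
  # the dashed geodesic of the example: midpoint (0, 0, 4/3)
  a <- t5_tree(-1, 1, 4 / 3); b <- t5_tree(1, -1, 4 / 3)
  expect_equal(t5_coords(geodesic_point(bhv_geodesic(a, b), 0.5)),
               c(0, 0, 4 / 3), tolerance = 1e-12)
  expect_error(geodesic_point(g12, 1.2), "lambda")
})

test_that("arc length accumulates linearly along geodesics", {
  set.seed(12)
  for (r in 1:10) {
    pr <- rand_pair(sample(5:8, 1))
    g <- bhv_geodesic(pr[[1]], pr[[2]])
    for (lam in c(0.15, 0.4, 0.5, 0.85)) {
      pt <- geodesic_point(g, lam)
      expect_equal(bhv_distance(pr[[1]], pt), lam * g$length,
                   tolerance = 1e-9)
      expect_equal(bhv_distance(pt, pr[[2]]), (1 - lam) * g$length,
                   tolerance = 1e-9)
    }
  }
})

test_that("the two forms of the squared-distance formula agree", {
  set.seed(13)
  for (r in 1:50) {
    pr <- rand_pair(sample(5:9, 1))
    s <- compute_support(pr[[1]], pr[[2]])
    ab <- sum(s$normA * s$normB)
    cd <- sum(s$C_xlen * s$C_ylen)
    d2_alt <- tree_norm(pr[[1]])^2 + tree_norm(pr[[2]])^2 + 2 * ab - 2 * cd
    expect_equal(s$length^2, d2_alt, tolerance = 1e-10)
  }
})

test_that("distances equal the brute-force support minimization", {
  set.seed(14)
  n <- 0
  while (n < 60) {
    pr <- rand_pair(sample(4:6, 1))
    s <- compute_support(pr[[1]], pr[[2]])
    if (n_incompatible(s) > 3 || n_incompatible(s) == 0) next
    n <- n + 1
    expect_equal(bhv_distance(pr[[1]], pr[[2]]),
                 brute_distance(pr[[1]], pr[[2]]), tolerance = 1e-10)
  }
})

test_that("the CAT(0) midpoint inequality holds", {
  set.seed(15)
  for (r in 1:300) {
    N <- sample(5:8, 1)
    x <- random_tree_gamma(N); y <- random_tree_gamma(N)
    z <- random_tree_gamma(N)
    g <- bhv_geodesic(x, y)
    m <- geodesic_point(g, 0.5)
    lhs <- bhv_distance(m, z)^2
    rhs <- 0.5 * bhv_distance(x, z)^2 + 0.5 * bhv_distance(y, z)^2 -
      0.25 * g$length^2
    expect_lte(lhs, rhs + 1e-10)
  }
})

test_that("supports are stable under small interior perturbations", {
  set.seed(16)
  for (r in 1:20) {
    pr <- rand_pair(6)
    s1 <- compute_support(pr[[1]], pr[[2]])
    x2 <- pr[[1]]
    x2$lengths <- x2$lengths * (1 + runif(length(x2$lengths), -1e-9, 1e-9))
    s2 <- compute_support(x2, pr[[2]])
    expect_identical(bhvpca:::support_key(s1), bhvpca:::support_key(s2))
  }
})

test_that("simplicity is flagged undefined for unresolved endpoints", {
  star <- bhv_tree(list(), numeric(0), 5)
  g <- bhv_geodesic(star, v5$v0)
  expect_warning(res <- is_simple(g), "resolved")
  expect_false(res)
})

test_that("geodesics serialize to a JSON-able record", {
  g <- bhv_geodesic(v5$v1, v5$v2)
  rec <- jsonlite::toJSON(list(length = g$length,
                               A = lapply(g$support$A, `[[`, "mask"),
                               B = lapply(g$support$B, `[[`, "mask"),
                               C = g$support$C_mask), auto_unbox = TRUE)
  expect_true(jsonlite::validate(rec))
})
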