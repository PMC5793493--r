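v5 <- fixture_t5()

test_that("weight vectors normalize and reject invalid input", {
  expect_equal(weight_vector(c(2, 1, 1)), c(0.5, 0.25, 0.25))
  expect_error(weight_vector(c(-1, 2)), "nonnegative")
  expect_error(weight_vector(c(0, 0)), "nonnegative")
})

test_that("the objective matches the closed-form squared distances", {
  p <- c(0.25, 0.35, 0.4)
  # a point in the top-left region of the example, where the squared
  # distances to the three vertices have explicit forms
  x <- t5_tree(-0.5, 0.8, 1.2)
  xi <- t5_coords(x)
  d0 <- (1 - xi[1])^2 + (1 - xi[2])^2 + (2 - xi[3])^2
  d1 <- (2 + xi[1])^2 + (1 - xi[2])^2 + (1 - xi[3])^2
  d2 <- (sqrt(5) + sqrt(xi[1]^2 + xi[2]^2))^2 + (1 - xi[3])^2
  expect_equal(omega(x, v5, p), sum(p * c(d0, d1, d2)), tolerance = 1e-12)
  # omega vanishes only at a fully weighted vertex
  expect_equal(omega(v5$v1, v5, c(0, 1, 0)), 0)
  expect_gt(omega(v5$v1, v5, c(1, 0, 0)), 0)
})

test_that("the gradient matches central finite differences", {
  set.seed(21)
  p <- c(0.25, 0.35, 0.4)
  for (x in list(t5_tree(-0.5, 0.8, 1.2), t5_tree(0.6, 0.7, 1.5),
                 t5_tree(0.4, -0.9, 1.1))) {
    g <- grad_omega(x, v5, p)
    fd <- vapply(seq_along(x$splits), function(j) {
      h <- 1e-7
      xp <- x; xp$lengths[j] <- xp$lengths[j] + h
      xm <- x; xm$lengths[j] <- xm$lengths[j] - h
      (omega(xp, v5, p) - omega(xm, v5, p)) / (2 * h)
    }, numeric(1))
    expect_equal(g, fd, tolerance = 1e-5)
  }
  # random interior configurations on larger trees
  for (r in 1:20) {
    V <- lapply(1:3, function(i) random_tree_gamma(6))
    x <- random_tree_gamma(6)
    p <- weight_vector(runif(3, 0.1, 1))
    g <- grad_omega(x, V, p)
    fd <- vapply(seq_along(x$splits), function(j) {
      h <- 1e-7
      xp <- x; xp$lengths[j] <- xp$lengths[j] + h
      xm <- x; xm$lengths[j] <- xm$lengths[j] - h
      (omega(xp, V, p) - omega(xm, V, p)) / (2 * h)
    }, numeric(1))
    expect_equal(g, fd, tolerance = 1e-4)
  }
})

test_that("the gradient vanishes at a converged mean", {
  p <- c(0.6, 0.2, 0.2)
  m <- frechet_mean(v5, p, eps = 1e-6, max_iter = 5e6)$mean
  expect_lt(max(abs(grad_omega(m, v5, p))), 1e-4)
})

test_that("the finite-difference Hessian of the objective is positive definite", {
  p <- c(0.25, 0.35, 0.4)
  for (x in list(t5_tree(-0.5, 0.8, 1.2), t5_tree(0.6, 0.7, 1.5))) {
    k <- length(x$splits)
    H <- matrix(0, k, k)
    for (j in seq_len(k)) {
      h <- 1e-5
      xp <- x; xp$lengths[j] <- xp$lengths[j] + h
      xm <- x; xm$lengths[j] <- xm$lengths[j] - h
      H[, j] <- (grad_omega(xp, v5, p) - grad_omega(xm, v5, p)) / (2 * h)
    }
    expect_true(all(eigen((H + t(H)) / 2, only.values = TRUE)$values > 0))
  }
})

test_that("means at basis weights recover the vertices", {
  for (i in 1:3) {
    p <- rep(0, 3); p[i] <- 1
    m <- frechet_mean(v5, p)
    expect_lt(bhv_distance(m$mean, v5[[i]]), 1e-9)
    expect_true(m$converged)
  }
  # all vertices equal: one effective vertex
  m <- frechet_mean(list(v5$v0, v5$v0), c(0.3, 0.7))
  expect_lt(bhv_distance(m$mean, v5$v0), 1e-9)
})

test_that("two-point means sit at geodesic midpoints", {
  m <- frechet_mean(v5[1:2], c(0.5, 0.5), eps = 1e-5, max_iter = 2e6)$mean
  mid <- geodesic_point(bhv_geodesic(v5$v0, v5$v1), 0.5)
  expect_lt(bhv_distance(m, mid), 1e-4)
})

test_that("single-orthant means equal the Euclidean weighted average", {
  set.seed(23)
  base <- random_tree_gamma(6)
  V <- lapply(1:3, function(i) {
    t <- base; t$lengths <- rgamma(length(t$lengths), 2, 10); t
  })
  p <- c(0.5, 0.3, 0.2)
  m <- frechet_mean(V, p, eps = 1e-6)
  expect_equal(m$mean$lengths,
               Reduce(`+`, Map(function(t, w) w * t$lengths, V, p)),
               tolerance = 1e-4)
  # pendant edges average as a Euclidean factor
  expect_equal(m$mean$pendant,
               Reduce(`+`, Map(function(t, w) w * t$pendant, V, p)),
               tolerance = 1e-12)
})

test_that("Sturm and cyclic means agree and weights are scale invariant", {
  set.seed(24)
  V <- lapply(1:3, function(i) random_tree_gamma(6))
  p <- c(0.2, 0.5, 0.3)
  mb <- frechet_mean(V, p, eps = 1e-5)
  ms <- frechet_mean(V, p, method = "sturm", eps = 1e-5, seed = 9)
  expect_lt(bhv_distance(mb$mean, ms$mean), 1e-3)
  mb2 <- frechet_mean(V, 7 * p, eps = 1e-5)
  expect_equal(mb$mean$lengths, mb2$mean$lengths)
})

test_that("non-convergence is reported when the iteration cap is hit", {
  m <- frechet_mean(v5, c(0.6, 0.2, 0.2), eps = 1e-12, max_iter = 50)
  expect_false(m$converged)
  expect_equal(m$iterations, 50)
})

test_that("the affine solution matches the plane and the iterative mean", {
  # at a vertex weight the solution is the vertex itself
  x0 <- t5_tree(0.4, 0.4, 1.6)
  la <- local_affine_solution(v5, c(1, 0, 0), x0)
  expect_equal(t5_coords(la), c(1, 1, 2), tolerance = 1e-12)
  # general weights: the plane xi = (p0-2p1+p2, p0+p1-2p2, 1+p0)
  p <- c(0.6, 0.2, 0.2)
  la <- local_affine_solution(v5, p, x0)
  expect_equal(t5_coords(la), t5_flat(p), tolerance = 1e-12)
  mb <- frechet_mean(v5, p, eps = 1e-5, max_iter = 5e6)$mean
  expect_lt(bhv_distance(la, mb), 1e-4)
  # non-simple supports are refused
  xc <- t5_tree(-0.3, 0.26, 1.2)
  expect_error(local_affine_solution(v5, p, xc), "not simple")
  # k = 1 in one orthant: linear interpolation of the endpoints
  set.seed(25)
  base <- random_tree_gamma(6)
  w <- base; w$lengths <- w$lengths * 2
  la <- local_affine_solution(list(base, w), c(0.25, 0.75), base)
  expect_equal(la$lengths, 0.25 * base$lengths + 0.75 * w$lengths,
               tolerance = 1e-12)
})

test_that("sticky configurations yield unresolved means without error", {
  set.seed(26)
  x <- random_tree_gamma(6)
  y <- nni(x, x$splits[1], 1, as_mask = TRUE)
  m <- frechet_mean(list(x, y), c(0.5, 0.5), eps = 1e-5)$mean
  expect_lte(length(m$splits), x$n - 2L)
})
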