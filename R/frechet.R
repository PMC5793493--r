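# Weighted Frechet means in tree space.  The mean of vertex trees
# V = {v_0, ..., v_k} with weights p in the k-simplex minimizes
# Omega(x, p) = sum_i p_i d(x, v_i)^2, and is unique because tree space is
# CAT(0).  Two iterative schemes are provided: Sturm's stochastic algorithm
# (vertex sampled with probability p_j, step 1/(i+2)) and a deterministic
# cyclic scheme in the spirit of Bacak (vertices used cyclically, weights
# absorbed into the step sizes).

#' Normalize a weight vector on the k-simplex
#'
#' Weights are nonnegative and normalized to sum to one; the Frechet mean is
#' invariant under positive scaling of the weights, so any positive scaling
#' is accepted.
#'
#' @param p numeric vector of nonnegative weights, not all zero.
#' @export
weight_vector <- function(p) {
  p <- as.numeric(p)
  if (any(p < 0) || all(p == 0) || anyNA(p)) {
    stop("weights must be nonnegative and not all zero")
  }
  p / sum(p)
}

check_config <- function(V, p) {
  if (length(V) < 1L) stop("need at least one vertex tree")
  for (v in V[-1]) check_leafset(V[[1]], v)
  p <- weight_vector(p)
  if (length(p) != length(V)) stop("one weight per vertex required")
  p
}

#' Weighted Frechet objective
#'
#' `Omega(x, p) = sum_i p_i d(x, v_i)^2`, the function whose unique
#' minimizer over tree space is the weighted Frechet mean.
#'
#' @param x a `bhv_tree`, the evaluation point.
#' @param V list of vertex trees.
#' @param p weights (normalized internally).
#' @param internal_only ignore pendant edges.
#' @export
omega <- function(x, V, p, internal_only = TRUE) {
  p <- check_config(V, p)
  d2 <- vapply(V, function(v) bhv_distance(x, v, internal_only)^2, numeric(1))
  sum(p * d2)
}

#' Gradient of the Frechet objective on an orthant interior
#'
#' For `x` fully resolved and interior to a mutual support region with
#' respect to all vertices, the partial derivative of `Omega` in the length
#' `x_j` of split `e_j` is
#' `2 x_j + 2 sum_i p_i { x_j ||B^(r_ij)|| / ||A^(r_ij)|| (1 - C_ij) - |e_j|_{v_i} C_ij }`,
#' where `C_ij` indicates that `e_j` belongs to the common part of the
#' support towards `v_i` and `r_ij` indexes the block of the support
#' containing `e_j` otherwise.  On support-region boundaries the objective
#' is continuous but not differentiable and the value returned here is the
#' one-sided expression for the support actually computed.
#'
#' @inheritParams omega
#' @return numeric vector of derivatives, one per internal split of `x`,
#'   in the order of `x$splits`.
#' @export
grad_omega <- function(x, V, p, internal_only = TRUE) {
  p <- check_config(V, p)
  if (!is_resolved(x)) stop("gradient is defined for fully resolved x only")
  g <- 2 * x$lengths
  for (i in seq_along(V)) {
    s <- compute_support(x, V[[i]], internal_only)
    for (j in seq_along(x$splits)) {
      m <- x$splits[j]
      ci <- match(m, s$C_mask)
      if (!is.na(ci)) {
        g[j] <- g[j] - 2 * p[i] * s$C_ylen[ci]
      } else {
        r <- which(vapply(s$A, function(b) m %in% b$mask, logical(1)))
        if (length(r) != 1L) stop("split not located in the support")
        g[j] <- g[j] + 2 * p[i] * x$lengths[j] * s$normB[r] / s$normA[r]
      }
    }
  }
  g
}

mean_pendant <- function(V, p) {
  pend <- Reduce(`+`, Map(function(v, w) w * v$pendant, V, p))
  root <- sum(vapply(V, function(v) v$root_edge, numeric(1)) * p)
  list(pendant = pend, root_edge = root)
}

run_mean <- function(V, p, method, eps, m, max_iter, internal_only, tol) {
  keep <- p > 0
  V <- V[keep]; p <- p[keep] / sum(p[keep])
  pm <- lapply(V, function(v) pack_tree(v, internal_only))
  masks <- lapply(pm, `[[`, "mask")
  lens <- lapply(pm, `[[`, "len")
  res <- if (method == "bacak") {
    cpp_mean_bacak(masks, lens, p, eps, m, max_iter, tol)
  } else {
    cpp_mean_sturm(masks, lens, p, eps, m, max_iter, tol)
  }
  mu <- unpack_tree(res, V[[1]], internal_only)
  if (internal_only) {
    mp <- mean_pendant(V, p)
    mu$pendant <- mp$pendant
    mu$root_edge <- mp$root_edge
  }
  list(mean = mu, iterations = res$iterations, converged = res$converged,
       final_step = res$final_step)
}

#' Weighted Frechet mean of a set of trees
#'
#' Iterates towards the minimizer of the weighted Frechet objective by
#' moving a fraction of the way along the geodesic to one vertex at a time.
#' `method = "bacak"` uses the vertices cyclically with steps
#' `s_i = p_j (k+1) / (i+2)` (deterministic; the default everywhere a mean
#' is needed internally); `method = "sturm"` samples vertex `j` with
#' probability `p_j` and steps `1/(i+2)`.  Iteration stops when the last
#' `m` iterates lie pairwise within `eps` of each other (implemented via
#' the step-length sum, which bounds the window diameter).
#'
#' Zero-weight vertices are dropped before iterating.  Pendant edges form a
#' Euclidean factor of tree space, so with `internal_only = TRUE` the mean's
#' pendant lengths are the weighted Euclidean averages.
#'
#' @param V list of vertex trees on a common leaf set.
#' @param p weights; default uniform.
#' @param method `"bacak"` (deterministic, default) or `"sturm"`.
#' @param eps convergence distance in tree-distance units.
#' @param m number of consecutive iterates that must agree.
#' @param max_iter iteration cap; exceeded means `converged = FALSE`.
#' @param seed optional integer seed (only the Sturm scheme draws random
#'   numbers).
#' @param internal_only ignore pendant edges in the metric.
#' @param tol support-computation tolerance.
#' @return a `bhv_mean`: list with `mean` (`bhv_tree`), `iterations`,
#'   `converged`, `final_step`, `objective`.
#' @examples
#' v <- fixture_t5()
#' m <- frechet_mean(v, c(1, 1, 0), eps = 1e-4)
#' # midpoint of the kinked geodesic: only the depth-1 split survives
#' @export
frechet_mean <- function(V, p = NULL, method = c("bacak", "sturm"),
                         eps = 1e-6, m = 5, max_iter = 1e5, seed = NULL,
                         internal_only = TRUE, tol = default_tol) {
  method <- match.arg(method)
  if (is.null(p)) p <- rep(1, length(V))
  p <- check_config(V, p)
  if (!is.null(seed)) set.seed(seed)
  res <- run_mean(V, p, method, eps, m, max_iter, internal_only, tol)
  res$objective <- omega(res$mean, V, p, internal_only)
  class(res) <- "bhv_mean"
  res
}

#' @export
print.bhv_mean <- function(x, ...) {
  cat("Frechet mean (", if (x$converged) "converged" else "NOT converged",
      " after ", x$iterations, " iterations, objective ",
      format(x$objective, digits = 8), ")\n", sep = "")
  print(x$mean)
  invisible(x)
}

#' Closed-form Frechet mean on a region where all geodesics are simple
#'
#' When the geodesics from a mutual support region to every vertex are
#' simple, each support block opposite a split `e_j` of the region's
#' topology is a singleton and the stationarity condition becomes linear:
#' `x_j = sum_i p_i ( C_ij |e_j|_{v_i} - (1 - C_ij) ||B^(r_ij)|| )`.
#' The locus of the Frechet mean is therefore an affine patch of dimension
#' at most `k` there.  The supports are read off at a reference point `x0`
#' inside the region.
#'
#' @param V list of vertex trees.
#' @param p weights.
#' @param x0 a fully resolved reference tree interior to the region.
#' @param internal_only ignore pendant edges.
#' @return a `bhv_tree` with the topology of `x0`; an error if any geodesic
#'   from `x0` to a vertex is not simple, and a warning if the solution
#'   leaves the orthant (a negative coordinate was truncated).
#' @export
local_affine_solution <- function(V, p, x0, internal_only = TRUE) {
  p <- check_config(V, p)
  geos <- lapply(V, function(v) bhv_geodesic(x0, v, internal_only))
  for (g in geos) {
    if (length(g$support$A) > 0 && !is_simple(g)) {
      stop("geodesic from the region to a vertex is not simple; ",
           "use frechet_mean() instead")
    }
  }
  xj <- numeric(length(x0$splits))
  for (j in seq_along(x0$splits)) {
    m <- x0$splits[j]
    acc <- 0
    for (i in seq_along(V)) {
      s <- geos[[i]]$support
      ci <- match(m, s$C_mask)
      if (!is.na(ci)) {
        acc <- acc + p[i] * s$C_ylen[ci]
      } else {
        r <- which(vapply(s$A, function(b) m %in% b$mask, logical(1)))
        acc <- acc - p[i] * s$normB[r]
      }
    }
    xj[j] <- acc
  }
  if (any(xj < 0)) {
    warning("affine solution leaves the orthant; the mean sits in another ",
            "region (negative coordinates truncated)")
    xj <- pmax(xj, 0)
  }
  mp <- mean_pendant(V, p)
  bhv_tree(x0$splits, xj, x0$n, labels = x0$labels,
           pendant = mp$pendant, root_edge = mp$root_edge)
}
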