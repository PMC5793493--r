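# The locus of the weighted Frechet mean, Pi(V): the image of the weight
# simplex under p -> mu(V, p).  Pi(V) contains the vertices and every
# vertex-pair geodesic, is compact, generally non-convex, and plays the
# role of a k-th principal component for tree data.  This file provides
# lattice sampling of Pi(V), projection of data trees onto it (exhaustive
# benchmark and fast geometric algorithm), and the fit summaries D^2 and
# the non-Euclidean r^2.

#' Triangular lattice on the weight simplex
#'
#' @param resolution lattice density `r`: points `(a, b, c)/r` with
#'   `a + b + c = r` for `k = 2` (and the analogue for `k = 1`).
#' @param k simplex dimension (1 or 2).
#' @return a matrix with `k + 1` columns, one lattice point per row.
#' @export
simplex_lattice <- function(resolution, k = 2) {
  r <- as.integer(resolution)
  if (k == 2) {
    pts <- list()
    for (a in 0:r) for (b in 0:(r - a)) {
      pts[[length(pts) + 1L]] <- c(a, b, r - a - b)
    }
    do.call(rbind, pts) / r
  } else if (k == 1) {
    cbind(0:r, r:0) / r
  } else stop("lattice sampling supports k = 1 or 2")
}

#' Sample the locus of the Frechet mean over a simplex lattice
#'
#' Computes the (cyclic-scheme) weighted Frechet mean at every point of a
#' triangular lattice on the weight simplex.  The three lattice corners
#' return the vertex trees themselves, and lattice points on a simplex edge
#' lie on the corresponding vertex-pair geodesic.
#'
#' @param V list of `k + 1` vertex trees (`k` at most 2).
#' @param resolution lattice density (default 32, i.e. spacing 1/32).
#' @param eps,m,max_iter convergence controls for the mean iteration.
#' @param internal_only ignore pendant edges.
#' @return list with `p` (lattice matrix) and `trees` (list of means).
#' @export
locus_sample <- function(V, resolution = 32, eps = 1e-6, m = 5,
                         max_iter = 1e5, internal_only = TRUE) {
  k <- length(V) - 1L
  L <- simplex_lattice(resolution, k)
  trees <- vector("list", nrow(L))
  for (i in seq_len(nrow(L))) {
    trees[[i]] <- frechet_mean(V, L[i, ], eps = eps, m = m,
                               max_iter = max_iter,
                               internal_only = internal_only)$mean
  }
  list(p = L, trees = trees)
}

dist_to_trees <- function(z, trees, internal_only = TRUE, tol = default_tol) {
  pz <- pack_tree(z, internal_only)
  pm <- lapply(trees, function(t) pack_tree(t, internal_only))
  cpp_dist_to_many(pz$mask, pz$len,
                   lapply(pm, `[[`, "mask"), lapply(pm, `[[`, "len"), tol)
}

projection_result <- function(projected, weights, distance,
                              iterations = NA_integer_, converged = TRUE) {
  structure(list(projected = projected, weights = weights,
                 distance = distance, iterations = iterations,
                 converged = converged),
            class = "bhv_projection")
}

#' @export
print.bhv_projection <- function(x, ...) {
  cat("Projection: distance", format(x$distance, digits = 8),
      "at p = (", paste(format(x$weights, digits = 4), collapse = ", "),
      ")\n")
  invisible(x)
}

#' Exhaustive-search projection onto the locus (benchmark)
#'
#' Minimizes `d(z, mu(V, p))` over a triangular lattice of weight vectors.
#' Computationally expensive and used as the benchmark for the geometric
#' projection algorithm.  The lattice means are first computed at a coarse
#' solver tolerance; all lattice points whose distance comes within
#' `margin` of the minimum are then recomputed at the fine tolerance and
#' the minimum re-taken, so the reported minimizer carries the fine
#' accuracy at a fraction of the cost.
#'
#' @param z the data tree to project.
#' @param V list of vertex trees.
#' @param resolution lattice density (default 32).
#' @param eps fine convergence tolerance for the candidate means.
#' @param eps_coarse coarse tolerance for the full lattice sweep.
#' @param margin distance margin (absolute) within which coarse lattice
#'   points are promoted to fine recomputation.
#' @param m,max_iter convergence controls.
#' @param internal_only ignore pendant edges.
#' @param lattice optionally a precomputed [locus_sample()] result to reuse
#'   across many data trees (its means are used as the coarse stage).
#' @param refine_levels number of local lattice-halving refinement levels
#'   around the near-minimal candidates (default 0: the plain lattice
#'   minimizer).  Each level runs a local search over simplex moves
#'   `h (e_i - e_j)` at the halved spacing, so `refine_levels = 3` locates
#'   the benchmark at an effective resolution eight times the global one.
#' @param refine_starts number of distinct near-minimal lattice cells from
#'   which the local descent is launched (the locus distance can have
#'   several local basins whose coarse values are within one cell of each
#'   other).
#' @param eps_refine solver tolerance for means evaluated during local
#'   refinement (the final benchmark point is recomputed at `eps`).
#' @return a `bhv_projection`: the minimizing mean tree, its weight
#'   vector, and the distance.
#' @export
project_exhaustive <- function(z, V, resolution = 32, eps = 1e-6,
                               eps_coarse = max(eps, 1e-2),
                               margin = 10 * eps_coarse,
                               m = 5, max_iter = 1e5, internal_only = TRUE,
                               lattice = NULL, refine_levels = 0,
                               refine_starts = 3, eps_refine = max(eps, 3e-3)) {
  if (is.null(lattice)) {
    lattice <- locus_sample(V, resolution, eps = eps_coarse, m = m,
                            max_iter = max_iter,
                            internal_only = internal_only)
  }
  d <- dist_to_trees(z, lattice$trees, internal_only)
  fine_mu <- function(p, e) frechet_mean(V, p, eps = e, m = m,
                                         max_iter = max_iter,
                                         internal_only = internal_only)$mean
  if (eps_coarse > eps) {
    cand <- which(d <= min(d) + margin)
    for (i in cand) {
      mu <- fine_mu(lattice$p[i, ], eps)
      lattice$trees[[i]] <- mu
      d[i] <- bhv_distance(z, mu, internal_only)
    }
  }
  best <- which.min(d)
  best_p <- lattice$p[best, ]
  best_tree <- lattice$trees[[best]]
  best_d <- d[best]

  if (refine_levels > 0) {
    k1 <- ncol(lattice$p)
    moves <- list()
    for (i in seq_len(k1)) for (j in seq_len(k1)) {
      if (i != j) {
        mv <- numeric(k1); mv[i] <- 1; mv[j] <- -1
        moves[[length(moves) + 1L]] <- mv
      }
    }
    cache <- new.env(parent = emptyenv())
    eval_p <- function(p) {
      key <- paste(round(p, 10), collapse = ",")
      got <- cache[[key]]
      if (!is.null(got)) return(got)
      val <- bhv_distance(z, fine_mu(p, eps_refine), internal_only)
      cache[[key]] <- val
      val
    }
    # launch the descent from the few best lattice cells: distinct local
    # basins can have coarse values within one cell size of each other
    ord <- order(d)
    starts <- ord[seq_len(min(refine_starts, length(ord)))]
    for (s in starts) {
      h <- 1 / resolution
      cur_p <- lattice$p[s, ]
      cur_d <- eval_p(cur_p)
      for (lev in seq_len(refine_levels)) {
        h <- h / 2
        repeat {
          improved <- FALSE
          for (mv in moves) {
            p <- cur_p + h * mv
            if (any(p < -1e-12)) next
            p <- pmax(p, 0); p <- p / sum(p)
            dd <- eval_p(p)
            if (dd < cur_d - 1e-12) {
              cur_p <- p; cur_d <- dd; improved <- TRUE
            }
          }
          if (!improved) break
        }
      }
      mu <- fine_mu(cur_p, eps)
      dd <- bhv_distance(z, mu, internal_only)
      if (dd < best_d) {
        best_p <- cur_p; best_tree <- mu; best_d <- dd
      }
    }
  }
  projection_result(best_tree, best_p, best_d)
}

perimeter_start <- function(V, internal_only = TRUE) {
  k1 <- length(V)
  pairs <- utils::combn(k1, 2)
  glist <- lapply(seq_len(ncol(pairs)), function(i) {
    bhv_geodesic(V[[pairs[1, i]]], V[[pairs[2, i]]], internal_only)
  })
  lens <- vapply(glist, `[[`, numeric(1), "length")
  if (sum(lens) == 0) return(V[[1]])
  e <- sample.int(length(glist), 1, prob = lens)
  geodesic_point(glist[[e]], runif(1))
}

#' Geometric projection onto the locus of the Frechet mean
#'
#' A greedy variant of Sturm's mean iteration: from the current estimate,
#' candidate points are placed a proportion `1/(i+2)` along the geodesics
#' to each vertex, the candidate nearest the data tree is kept, and the
#' weight estimate counts how often each vertex was chosen.  The initial
#' point is sampled uniformly (by arc length) from the perimeter of the
#' locus.  Convergence testing matches [frechet_mean()].  Because the
#' locus is not convex the iteration can stop in a local minimum of the
#' perpendicular distance; `restarts` keeps the best of several starts.
#'
#' @param z the data tree to project.
#' @param V list of vertex trees.
#' @param seed optional integer seed (controls the start point).
#' @param eps,m,max_iter convergence controls.
#' @param restarts number of independent starts; the result with the
#'   smallest distance is returned.
#' @param internal_only ignore pendant edges.
#' @return a `bhv_projection` (with `iterations` and `converged` fields).
#' @export
project_geometric <- function(z, V, seed = NULL, eps = 1e-6, m = 5,
                              max_iter = 1e5, restarts = 1,
                              internal_only = TRUE) {
  check_leafset(z, V[[1]])
  if (!is.null(seed)) set.seed(seed)
  pm <- lapply(V, function(v) pack_tree(v, internal_only))
  masks <- lapply(pm, `[[`, "mask")
  lens <- lapply(pm, `[[`, "len")
  pz <- pack_tree(z, internal_only)
  best <- NULL
  for (r in seq_len(restarts)) {
    mu0 <- perimeter_start(V, internal_only)
    p0 <- pack_tree(mu0, internal_only)
    res <- cpp_project(pz$mask, pz$len, masks, lens, p0$mask, p0$len,
                       eps, m, max_iter, default_tol)
    if (is.null(best) || res$distance < best$distance) best <- res
  }
  proj <- unpack_tree(best, V[[1]], internal_only)
  if (internal_only) {
    mp <- mean_pendant(V, weight_vector(pmax(best$weights, 1e-12)))
    proj$pendant <- mp$pendant
    proj$root_edge <- mp$root_edge
  }
  projection_result(proj, best$weights, best$distance,
                    best$iterations, best$converged)
}

#' Sum of squared projection distances of a data set
#'
#' `D^2_Z(Pi(V)) = sum_i d(z_i, Pi(V))^2`, with projections computed by the
#' geometric algorithm (default) or the exhaustive benchmark.  The
#' projections themselves are attached as an attribute.
#'
#' @param Z list of data trees.
#' @param V list of vertex trees.
#' @param method `"geometric"` or `"exhaustive"`.
#' @param ... passed to the projection function.
#' @param internal_only ignore pendant edges.
#' @return the sum of squared distances, with attribute `"projections"`
#'   (a list of `bhv_projection`) and `"failed"` (indices of data points
#'   whose projection did not converge).
#' @export
sum_squared_projected <- function(Z, V, method = c("geometric", "exhaustive"),
                                  ..., internal_only = TRUE) {
  method <- match.arg(method)
  f <- if (method == "geometric") project_geometric else project_exhaustive
  projections <- lapply(Z, f, V = V, internal_only = internal_only, ...)
  d2 <- sum(vapply(projections, `[[`, numeric(1), "distance")^2)
  failed <- which(!vapply(projections, `[[`, logical(1), "converged"))
  if (length(failed)) {
    warning(length(failed), " projection(s) did not converge")
  }
  structure(d2, projections = projections, failed = failed)
}

#' Non-Euclidean proportion-of-variance statistic
#'
#' With residual `R = sum_i d(z_i, pi(z_i))^2` and dispersion
#' `E = sum_i d(pi_bar, pi(z_i))^2` (where `pi_bar` is the Frechet mean of
#' the projections), `mode = "explained"` (default) returns `E / (R + E)`,
#' which behaves as a proportion of variance explained; `mode = "literal"`
#' returns `R / (R + E)`.  Both are exposed because the two forms disagree
#' about which term sits in the numerator while only the first matches the
#' "proportion of variance explained" reading; see the package vignette.
#'
#' @param Z list of data trees.
#' @param V list of vertex trees.
#' @param mode `"explained"` or `"literal"`.
#' @param projections optionally reuse projections (e.g. the attribute of
#'   [sum_squared_projected()]).
#' @param internal_only ignore pendant edges.
#' @param ... passed to [project_geometric()].
#' @return a number in `[0, 1]`; when all projections coincide the
#'   dispersion term vanishes and the value 0 carries attribute
#'   `"degenerate" = TRUE`.
#' @export
r_squared <- function(Z, V, mode = c("explained", "literal"),
                      projections = NULL, internal_only = TRUE, ...) {
  mode <- match.arg(mode)
  if (is.null(projections)) {
    projections <- attr(sum_squared_projected(Z, V, internal_only = internal_only,
                                              ...), "projections")
  }
  proj_trees <- lapply(projections, `[[`, "projected")
  resid <- sum(vapply(projections, `[[`, numeric(1), "distance")^2)
  pibar <- frechet_mean(proj_trees, eps = 1e-4,
                        internal_only = internal_only)$mean
  expl <- sum(dist_to_trees(pibar, proj_trees, internal_only)^2)
  tot <- resid + expl
  if (tot == 0 || expl <= 1e-10 * tot) {
    # all projections (numerically) coincide: no dispersion to explain
    return(structure(0, degenerate = TRUE))
  }
  if (mode == "explained") expl / tot else resid / tot
}

#' Topology map of the locus over the weight simplex
#'
#' Labels every lattice point of the simplex with the topology of the
#' corresponding point of the locus, suitable for shading the simplex by
#' orthant (sticky regions show up as repeated unresolved topologies over
#' sets of positive area).
#'
#' @param V list of 3 vertex trees (`k = 2`).
#' @param resolution lattice density.
#' @param ... passed to [locus_sample()].
#' @return a data frame with columns `p0, p1, p2`, `topology` (key), and
#'   `newick`.
#' @export
simplex_topology_map <- function(V, resolution = 16, ...) {
  if (length(V) != 3L) stop("the topology map is drawn for k = 2")
  ls <- locus_sample(V, resolution, ...)
  data.frame(p0 = ls$p[, 1], p1 = ls$p[, 2], p2 = ls$p[, 3],
             topology = vapply(ls$trees, topology_key, character(1)),
             newick = vapply(ls$trees, write_newick, character(1)),
             stringsAsFactors = FALSE)
}
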