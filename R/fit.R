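# Fitting the locus Pi(V) to a dataset: greedy stochastic optimization over
# vertex configurations.  One vertex at a time is perturbed by a proposal
# distribution; a proposed configuration replaces the current one whenever
# it lowers the sum of squared projection distances.

#' Proposal distributions for vertex moves
#'
#' Three families are available: `"data_sample"` draws a tree uniformly
#' with replacement from the dataset; `"beta_interpolate"` draws a dataset
#' tree `z` and moves a Beta(`shape1`, `shape2`)-distributed proportion of
#' the way along the geodesic from the current vertex to `z`;
#' `"random_walk"` runs a random walk from the current vertex (see
#' [random_walk_tree()]).
#'
#' @param kind one of `"data_sample"`, `"beta_interpolate"`,
#'   `"random_walk"`.
#' @param shape1,shape2 beta parameters for `"beta_interpolate"`.
#' @param steps,step_size random-walk parameters; `step_size = NULL` means
#'   a fraction `step_frac` of the dataset's mean internal edge length.
#' @param step_frac see above.
#' @return a `proposal_spec` object.
#' @export
proposal_spec <- function(kind = c("data_sample", "beta_interpolate",
                                   "random_walk"),
                          shape1 = 2, shape2 = 2,
                          steps = 1, step_size = NULL, step_frac = 0.05) {
  kind <- match.arg(kind)
  if (shape1 <= 0 || shape2 <= 0 || steps <= 0 || step_frac <= 0 ||
      (!is.null(step_size) && step_size <= 0)) {
    stop("proposal parameters must be positive")
  }
  structure(list(kind = kind, shape1 = shape1, shape2 = shape2,
                 steps = steps, step_size = step_size,
                 step_frac = step_frac),
            class = "proposal_spec")
}

#' Default proposal set for locus fitting
#'
#' A data-sample proposal, a Beta(2,2) geodesic interpolation, one long-step
#' walk and one multi-step small-step walk, with walk scales tied to the
#' dataset's mean internal edge length.
#'
#' @export
default_proposals <- function() {
  list(proposal_spec("data_sample"),
       proposal_spec("beta_interpolate", shape1 = 2, shape2 = 2),
       proposal_spec("random_walk", steps = 1, step_frac = 0.20),
       proposal_spec("random_walk", steps = 5, step_frac = 0.05))
}

mean_internal_edge <- function(Z) {
  mean(unlist(lapply(Z, `[[`, "lengths")))
}

#' Draw one proposed vertex tree
#'
#' @param spec a [proposal_spec()].
#' @param v current vertex tree.
#' @param Z dataset (needed by the data-based proposals).
#' @param seed optional seed.
#' @param internal_only ignore pendant edges for geodesic interpolation.
#' @export
propose <- function(spec, v, Z, seed = NULL, internal_only = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  switch(spec$kind,
    data_sample = Z[[sample.int(length(Z), 1)]],
    beta_interpolate = {
      z <- Z[[sample.int(length(Z), 1)]]
      t <- rbeta(1, spec$shape1, spec$shape2)
      geodesic_point(bhv_geodesic(v, z, internal_only), t)
    },
    random_walk = {
      ss <- if (is.null(spec$step_size)) spec$step_frac * mean_internal_edge(Z)
            else spec$step_size
      random_walk_tree(v, spec$steps, ss)
    })
}

d2_eval <- function(Z, V, eps, m, max_iter, internal_only, bail = Inf) {
  # early abandon: a candidate that already exceeds the incumbent D^2
  # cannot be accepted, so the remaining projections are skipped
  projections <- vector("list", length(Z))
  d2 <- 0
  for (i in seq_along(Z)) {
    pr <- project_geometric(Z[[i]], V, eps = eps, m = m, max_iter = max_iter,
                            internal_only = internal_only)
    projections[[i]] <- pr
    d2 <- d2 + pr$distance^2
    if (d2 >= bail) return(list(d2 = Inf, projections = NULL))
  }
  list(d2 = d2, projections = projections)
}

#' Fit the locus of the Frechet mean to a dataset
#'
#' Greedy stochastic search over vertex configurations (`k = 2`): each
#' sweep visits the three vertices in turn, draws one candidate from each
#' proposal, evaluates the sum of squared projection distances of the
#' dataset onto the candidate locus with the geometric projection
#' algorithm, and accepts whenever the sum decreases.  The search stops
#' when the relative improvement over a window of sweeps falls below
#' `conv_tol`.  Because the objective is non-convex, several independent
#' runs are performed and the best is kept.
#'
#' @param Z list of data trees.
#' @param k locus dimension; only `k = 2` is supported.
#' @param proposals list of [proposal_spec()] objects.
#' @param V_init optional initial vertex list; default three distinct
#'   uniform draws from `Z` (fresh draws per run).
#' @param seed optional integer seed.
#' @param runs independent restarts (default 3).
#' @param eps,m,max_iter projection convergence controls.
#' @param conv_tol,conv_window stop when the relative decrease of the
#'   objective over `conv_window` sweeps is below `conv_tol`.
#' @param max_sweeps hard cap on sweeps per run.
#' @param internal_only ignore pendant edges.
#' @return a `bhv_fit`: list with `best` (list `V`, `projections`,
#'   `d_squared`, `r_squared`), `trace` (accepted objective values by
#'   sweep across runs), `runs`, `seeds`.
#' @export
fit_locus <- function(Z, k = 2, proposals = default_proposals(),
                      V_init = NULL, seed = NULL, runs = 3,
                      eps = 1e-3, m = 5, max_iter = 1e5,
                      conv_tol = 1e-3, conv_window = 10, max_sweeps = 100,
                      internal_only = TRUE) {
  if (length(Z) == 0) stop("empty dataset")
  if (k != 2) stop("only k = 2 fitting is supported")
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max %/% 2, runs)
  best <- NULL
  trace <- list()
  for (run in seq_len(runs)) {
    set.seed(seeds[run])
    V <- if (is.null(V_init)) {
      idx <- sample.int(length(Z), min(3, length(Z)))
      while (length(unique(idx)) < 3 && length(Z) >= 3) {
        idx <- sample.int(length(Z), 3)
      }
      Z[idx]
    } else V_init
    cur <- d2_eval(Z, V, eps, m, max_iter, internal_only)
    hist <- cur$d2
    sweep <- 0
    repeat {
      sweep <- sweep + 1
      for (i in seq_along(V)) {
        for (spec in proposals) {
          w <- propose(spec, V[[i]], Z, internal_only = internal_only)
          Vp <- V; Vp[[i]] <- w
          cand <- d2_eval(Z, Vp, eps, m, max_iter, internal_only,
                          bail = cur$d2)
          if (cand$d2 < cur$d2) {
            V <- Vp; cur <- cand
          }
        }
      }
      hist <- c(hist, cur$d2)
      trace[[length(trace) + 1L]] <- data.frame(run = run, sweep = sweep,
                                                d_squared = cur$d2)
      if (sweep >= conv_window) {
        ref <- hist[length(hist) - conv_window]
        if (ref <= 0 || (ref - cur$d2) / ref < conv_tol) break
      }
      if (sweep >= max_sweeps) break
    }
    if (is.null(best) || cur$d2 < best$d_squared) {
      best <- list(V = V, projections = cur$projections, d_squared = cur$d2)
    }
  }
  if (is.null(best$projections)) {  # D^2 == 0 shortcut never stored them
    best$projections <- d2_eval(Z, best$V, eps, m, max_iter,
                                internal_only)$projections
  }
  best$r_squared <- r_squared(Z, best$V, projections = best$projections,
                              internal_only = internal_only)
  structure(list(best = best, trace = do.call(rbind, trace),
                 runs = runs, seeds = seeds),
            class = "bhv_fit")
}

#' @export
print.bhv_fit <- function(x, ...) {
  cat("Locus fit over", x$runs, "run(s):\n")
  cat("  D^2 =", format(x$best$d_squared, digits = 6),
      "  r^2 =", format(x$best$r_squared, digits = 4), "\n")
  invisible(x)
}
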