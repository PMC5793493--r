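# Geodesics between points of BHV tree space.  The support of the geodesic
# between x and y is the triple (A, B, C): ordered blocks A^(1)..A^(l) of
# splits of x and B^(1)..B^(l) of splits of y that are dropped/picked up as
# the path is traversed, plus the set C of splits compatible with everything
# in both trees (these interpolate linearly, as does the Euclidean pendant
# factor).  The squared length is sum_l (||A^(l)|| + ||B^(l)||)^2 + ||C - D||^2.

default_tol <- 1e-12

#' Geodesic between two trees
#'
#' Computes the unique geodesic between two points of tree space via the
#' polynomial-time geodesic tree path construction: starting from the cone
#' path, blocks are successively refined whenever a minimum-weight vertex
#' cover of the bipartite incompatibility graph (solved by max-flow) has
#' weight below one.
#'
#' @param x,y trees on the same leaf set (`bhv_tree`).
#' @param internal_only ignore pendant edges (the default for all analyses
#'   here); if `FALSE` pendant edges join the common part of the support.
#' @param tol absolute tolerance for cover-weight and ratio comparisons.
#' @return an object of class `bhv_geodesic` with elements `x`, `y`,
#'   `support` (`A`, `B` as lists of split-mask vectors, `C_mask`),
#'   and `length`.
#' @export
bhv_geodesic <- function(x, y, internal_only = TRUE, tol = default_tol) {
  check_leafset(x, y)
  px <- pack_tree(x, internal_only)
  py <- pack_tree(y, internal_only)
  s <- cpp_support(px$mask, px$len, py$mask, py$len, tol)
  structure(list(x = x, y = y, internal_only = internal_only,
                 support = s, length = s$length, tol = tol),
            class = "bhv_geodesic")
}

#' @export
print.bhv_geodesic <- function(x, ...) {
  l <- length(x$support$A)
  cat("BHV geodesic: length", format(x$length, digits = 8),
      "|", l, "support block(s),", length(x$support$C_mask),
      "common split(s)\n")
  invisible(x)
}

#' Geodesic support of a pair of trees
#'
#' The support characterizes the sequence of orthants the geodesic
#' traverses; trees lying in the same support region with respect to a
#' reference point have equal supports.
#'
#' @inheritParams bhv_geodesic
#' @return list with `A`, `B` (ordered lists of split blocks, each a vector
#'   of masks with lengths), `C_mask`, `C_xlen`, `C_ylen`, block norms and
#'   the geodesic `length`.
#' @export
compute_support <- function(x, y, internal_only = TRUE, tol = default_tol) {
  bhv_geodesic(x, y, internal_only, tol)$support
}

support_key <- function(s) {
  blk <- function(b) paste(sort(b$mask), collapse = ",")
  paste(c(vapply(s$A, blk, character(1)), "/",
          vapply(s$B, blk, character(1))), collapse = ";")
}

#' Do two geodesics share the same support?
#' @param g1,g2 `bhv_geodesic` objects with a common first endpoint.
#' @export
same_support <- function(g1, g2) {
  identical(support_key(g1$support), support_key(g2$support))
}

#' BHV distance between two trees
#'
#' @inheritParams bhv_geodesic
#' @return the geodesic distance, a nonnegative number.
#' @examples
#' v <- fixture_t5()
#' bhv_distance(v[[2]], v[[3]])  # 2 * sqrt(5): the cone path of the example
#' @export
bhv_distance <- function(x, y, internal_only = TRUE, tol = default_tol) {
  check_leafset(x, y)
  px <- pack_tree(x, internal_only)
  py <- pack_tree(y, internal_only)
  cpp_distance(px$mask, px$len, py$mask, py$len, tol)
}

#' Point at a given arc-length fraction along a geodesic
#'
#' Common splits interpolate linearly; the splits of block `i` of the
#' support vanish (and the opposite block's splits appear) at the breakpoint
#' `||A^(i)|| / (||A^(i)|| + ||B^(i)||)`.
#'
#' @param g a `bhv_geodesic`.
#' @param lambda arc-length fraction in `[0, 1]`.
#' @return a `bhv_tree`: the tree at fraction `lambda` from `x` to `y`.
#' @export
geodesic_point <- function(g, lambda) {
  if (!inherits(g, "bhv_geodesic")) stop("need a bhv_geodesic")
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  px <- pack_tree(g$x, g$internal_only)
  py <- pack_tree(g$y, g$internal_only)
  pt <- cpp_geodesic_point(px$mask, px$len, py$mask, py$len, lambda, g$tol)
  out <- unpack_tree(pt, g$x, g$internal_only)
  if (g$internal_only) {
    # pendant edges form a Euclidean factor and interpolate linearly
    out$pendant <- (1 - lambda) * g$x$pendant + lambda * g$y$pendant
  }
  out
}

#' Is a geodesic simple?
#'
#' A geodesic between fully resolved trees is simple when every support
#' block contains exactly one split on each side, i.e. at most one edge
#' length at a time contracts to zero along the path.  For unresolved
#' endpoints the notion is not defined and `FALSE` is returned with a
#' warning.
#'
#' @param g a `bhv_geodesic`.
#' @export
is_simple <- function(g) {
  if (!is_resolved(g$x) || !is_resolved(g$y)) {
    warning("simplicity is defined for fully resolved endpoints only")
    return(FALSE)
  }
  all(vapply(g$support$A, function(b) length(b$mask) == 1L, logical(1))) &&
    all(vapply(g$support$B, function(b) length(b$mask) == 1L, logical(1)))
}

#' @rdname compute_support
#' @export
support_of <- compute_support
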