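#' @useDynLib bhvpca, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm rgamma rexp runif rbeta setNames
#' @importFrom utils write.table head
NULL

# Splits are bitmasks over the non-root leaves 1..N: bit i-1 <-> leaf i.
# The root leaf 0 is never part of a stored split, which makes the
# representation canonical (the stored side is the side away from the root).

split_mask <- function(leaves, n) {
  leaves <- as.integer(leaves)
  if (length(leaves) == 0L) stop("a split must contain at least one leaf")
  if (any(leaves < 1L | leaves > n)) {
    stop("split leaves must lie in 1..N (the root leaf 0 is never stored)")
  }
  if (anyDuplicated(leaves)) stop("duplicated leaf in split")
  sum(bitwShiftL(1L, leaves - 1L))
}

mask_leaves <- function(mask, n) which(bitwAnd(bitwShiftR(mask, 0:(n - 1L)), 1L) == 1L)

mask_size <- function(mask) {
  k <- 0L
  while (mask > 0L) {
    k <- k + bitwAnd(mask, 1L)
    mask <- bitwShiftR(mask, 1L)
  }
  k
}

#' Test compatibility of two splits
#'
#' Two splits of a common leaf set can occur in the same tree exactly when
#' one of the four pairwise intersections of their sides is empty.  With both
#' splits stored canonically as the side away from the root leaf, this
#' reduces to the two sides being nested or disjoint.
#'
#' @param a,b integer vectors of leaves (in `1..n`) on the non-root side of
#'   each split, or single precomputed bitmasks (see `as_mask`).
#' @param n number of non-root leaves of the underlying leaf set `{0,...,n}`.
#' @param as_mask if `TRUE`, `a` and `b` are already bitmasks.
#' @return `TRUE` if the splits are compatible.
#' @examples
#' split_compatible(c(4, 5), c(3, 4, 5), n = 5)  # nested: TRUE
#' split_compatible(c(3, 4, 5), c(2, 3, 4), n = 5)  # FALSE
#' @export
split_compatible <- function(a, b, n, as_mask = FALSE) {
  if (as_mask) {
    ma <- as.integer(a); mb <- as.integer(b)
  } else {
    ma <- split_mask(a, n); mb <- split_mask(b, n)
  }
  cpp_compat(ma, mb)
}

#' Check that a collection of splits forms a valid tree topology
#'
#' Any collection of pairwise compatible splits determines a tree topology;
#' a topology on the leaf set `{0,...,n}` can contain at most `n - 2`
#' internal splits.  The empty collection is the star tree.
#'
#' @param splits a list of integer vectors, each the non-root side of an
#'   internal split (size at least 2).
#' @param n number of non-root leaves.
#' @return `TRUE` or `FALSE`; a pure predicate, never an error for
#'   well-formed input.
#' @export
validate_topology <- function(splits, n) {
  if (length(splits) == 0L) return(TRUE)
  masks <- vapply(splits, split_mask, integer(1), n = n)
  sizes <- vapply(masks, mask_size, integer(1))
  if (any(sizes < 2L) || any(sizes > n - 1L)) return(FALSE)
  if (anyDuplicated(masks)) return(FALSE)
  if (length(masks) > n - 2L) return(FALSE)
  for (i in seq_along(masks)) {
    for (j in seq_len(i - 1L)) {
      if (!cpp_compat(masks[i], masks[j])) return(FALSE)
    }
  }
  TRUE
}

#' Construct a phylogenetic tree as a point in BHV tree space
#'
#' A tree on the leaf set `{0,...,n}` (leaf 0 is the root) is determined by
#' its internal splits with strictly positive lengths, together with pendant
#' edge lengths for leaves `1..n`.  The root edge carries no weight.
#'
#' @param splits list of integer vectors (non-root sides of internal splits),
#'   or an integer vector of precomputed bitmasks.
#' @param lengths positive numeric vector, one length per split.
#' @param n number of non-root leaves.
#' @param labels character vector of `n + 1` leaf labels, the first being
#'   the root; defaults to `"0" ... "n"`.
#' @param pendant pendant edge lengths for leaves `1..n` (default 1).
#' @param root_edge length of the (unweighted, ignored) root edge kept only
#'   for faithful Newick round-trips.
#' @return an object of class `bhv_tree`.
#' @export
bhv_tree <- function(splits, lengths, n, labels = NULL, pendant = NULL,
                     root_edge = 0) {
  if (is.list(splits)) {
    masks <- vapply(splits, split_mask, integer(1), n = n)
  } else {
    masks <- as.integer(splits)
  }
  lengths <- as.numeric(lengths)
  if (length(masks) != length(lengths)) stop("splits and lengths differ in length")
  keep <- lengths > 0
  masks <- masks[keep]; lengths <- lengths[keep]
  if (any(vapply(masks, mask_size, integer(1)) < 2L)) {
    stop("internal splits must contain at least two leaves")
  }
  o <- order(masks)
  masks <- masks[o]; lengths <- lengths[o]
  if (anyDuplicated(masks)) stop("duplicated split")
  if (length(masks) > n - 2L) stop("too many internal splits for ", n + 1L, " leaves")
  for (i in seq_along(masks)) {
    for (j in seq_len(i - 1L)) {
      if (!cpp_compat(masks[i], masks[j])) {
        stop("incompatible splits {", paste(mask_leaves(masks[i], n), collapse = ","),
             "} and {", paste(mask_leaves(masks[j], n), collapse = ","), "}")
      }
    }
  }
  if (is.null(labels)) labels <- as.character(0:n)
  if (length(labels) != n + 1L) stop("need ", n + 1L, " leaf labels")
  if (is.null(pendant)) pendant <- rep(1, n)
  structure(list(n = n, labels = labels, splits = masks, lengths = lengths,
                 pendant = as.numeric(pendant), root_edge = root_edge),
            class = "bhv_tree")
}

#' @export
print.bhv_tree <- function(x, ...) {
  cat("BHV tree on", x$n + 1L, "leaves (root:", x$labels[1], ")\n")
  if (length(x$splits) == 0L) {
    cat("  star tree (no internal splits)\n")
  } else {
    for (i in seq_along(x$splits)) {
      lv <- mask_leaves(x$splits[i], x$n)
      cat("  {", paste(x$labels[lv + 1L], collapse = ","), "} : ",
          format(x$lengths[i], digits = 6), "\n", sep = "")
    }
  }
  invisible(x)
}

#' @export
format.bhv_tree <- function(x, ...) write_newick(x)

is_resolved <- function(x) length(x$splits) == x$n - 2L

#' Number of internal splits and resolution status
#' @param x a `bhv_tree`.
#' @return logical: is the tree fully resolved (binary)?
#' @export
fully_resolved <- function(x) is_resolved(x)

#' Length of a split in a tree
#'
#' Returns the branch length of the given split, or zero when the split is
#' not contained in the tree (the standard convention in tree space).
#'
#' @param x a `bhv_tree`.
#' @param leaves non-root side of the split as a vector of leaf indices.
#' @export
split_length <- function(x, leaves) {
  m <- split_mask(leaves, x$n)
  i <- match(m, x$splits)
  if (is.na(i)) 0 else x$lengths[i]
}

#' Norm of a tree
#'
#' The square root of the sum of squared edge lengths, over internal edges
#' only (the default, matching how all analyses here treat pendant edges) or
#' over internal plus pendant edges.
#'
#' @param x a `bhv_tree`.
#' @param internal_only include only internal edges?
#' @export
tree_norm <- function(x, internal_only = TRUE) {
  s <- sum(x$lengths^2)
  if (!internal_only) s <- s + sum(x$pendant^2)
  sqrt(s)
}

total_internal_length <- function(x) sum(x$lengths)

# packed representation handed to the C++ kernels; pendant edges enter as
# singleton splits (always mutually compatible, hence always common)
pack_tree <- function(x, internal_only = TRUE) {
  if (internal_only) {
    list(mask = x$splits, len = x$lengths)
  } else {
    list(mask = c(x$splits, bitwShiftL(1L, 0:(x$n - 1L))),
         len = c(x$lengths, x$pendant))
  }
}

unpack_tree <- function(packed, template, internal_only = TRUE) {
  m <- packed$mask; l <- packed$len
  n <- template$n
  pend <- template$pendant
  sizes <- vapply(m, mask_size, integer(1))
  if (!internal_only) {
    single <- sizes == 1L
    if (any(single)) {
      idx <- vapply(m[single], function(mm) which(bitwAnd(mm, bitwShiftL(1L, 0:(n - 1L))) != 0L), integer(1))
      pend <- rep(0, n)
      pend[idx] <- l[single]
    }
    m <- m[!single]; l <- l[!single]
  }
  bhv_tree(m, l, n, labels = template$labels, pendant = pend,
           root_edge = template$root_edge)
}

same_leafset <- function(x, y) {
  x$n == y$n && identical(x$labels, y$labels)
}

check_leafset <- function(x, y) {
  if (!same_leafset(x, y)) stop("trees are defined on different leaf sets")
  invisible(TRUE)
}

#' Topology of a tree
#'
#' @param x a `bhv_tree`.
#' @return a character key identifying the orthant of the tree: the sorted
#'   internal splits rendered as sorted leaf lists.
#' @export
topology_key <- function(x) {
  if (length(x$splits) == 0L) return("*")
  paste(vapply(sort(x$splits), function(m) {
    paste(mask_leaves(m, x$n), collapse = ",")
  }, character(1)), collapse = "|")
}
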