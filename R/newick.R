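# Newick input/output.  Parsing is delegated to ape; trees are then
# re-expressed in the canonical split representation relative to the root
# leaf.  Writing is done directly from the split containment order.

order_labels <- function(labels) {
  if (all(grepl("^[0-9]+$", labels))) labels[order(as.numeric(labels))]
  else sort(labels)
}

phylo_to_bhv <- function(tr, root_label = NULL) {
  if (is.null(tr$edge.length)) stop("branch lengths are mandatory")
  if (anyNA(tr$edge.length)) stop("every edge needs a branch length")
  if (any(tr$edge.length < 0)) stop("negative branch length")
  tr <- ape::collapse.singles(tr)
  if (ape::Ntip(tr) < 3L) stop("need at least 3 leaves")
  if (ape::is.rooted(tr)) tr <- ape::unroot(tr)

  tips <- tr$tip.label
  if (is.null(root_label)) {
    root_label <- if ("0" %in% tips) "0" else order_labels(tips)[1]
  }
  if (!root_label %in% tips) stop("root label '", root_label, "' not among leaves")
  n <- length(tips) - 1L
  labels <- c(root_label, order_labels(setdiff(tips, root_label)))
  leaf_index <- setNames(seq_len(n), labels[-1])  # non-root leaves -> 1..n
  full <- sum(bitwShiftL(1L, 0:(n - 1L)))

  tr <- stats::reorder(tr, "postorder")
  ntip <- ape::Ntip(tr)
  nnode <- tr$Nnode
  below <- integer(ntip + nnode)     # bitmask of non-root tips below each node
  hasroot <- logical(ntip + nnode)
  for (i in seq_len(ntip)) {
    lab <- tr$tip.label[i]
    if (lab == root_label) hasroot[i] <- TRUE
    else below[i] <- bitwShiftL(1L, leaf_index[[lab]] - 1L)
  }
  masks <- integer(0); lens <- numeric(0)
  pendant <- rep(NA_real_, n)
  root_edge <- 0
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
    below[par] <- bitwOr(below[par], below[ch])
    hasroot[par] <- hasroot[par] || hasroot[ch]
    len <- tr$edge.length[e]
    if (ch <= ntip) {
      if (hasroot[ch]) root_edge <- len
      else pendant[leaf_index[[tr$tip.label[ch]]]] <- len
    } else {
      away <- if (hasroot[ch]) bitwAnd(full, bitwNot(below[ch])) else below[ch]
      if (len > 0) {
        masks <- c(masks, away); lens <- c(lens, len)
      } # zero-length internal edges are contracted on parse
    }
  }
  bhv_tree(masks, lens, n, labels = labels, pendant = pendant,
           root_edge = root_edge)
}

#' Parse a rooted Newick string into a BHV tree
#'
#' The tree is re-expressed by its splits, stored canonically as the leaf
#' side away from the designated root leaf.  Branch lengths are mandatory;
#' zero-length internal edges are contracted (the tree then sits on an
#' orthant boundary); degree-2 vertices are suppressed with lengths summed.
#'
#' @param text a Newick string.
#' @param root_label label of the leaf taken as the root; defaults to
#'   `"0"` when present, otherwise the first label in sorted order.
#' @return a [bhv_tree()].
#' @examples
#' t <- parse_newick("((1:1,2:1):0.5,(3:1,4:1):0.5,0:1);")
#' length(t$splits)  # 2 internal splits
#' @export
parse_newick <- function(text, root_label = NULL) {
  text <- trimws(text)
  bal <- cumsum(ifelse(strsplit(text, "")[[1]] == "(", 1L,
                       ifelse(strsplit(text, "")[[1]] == ")", -1L, 0L)))
  if (any(bal < 0L)) {
    stop("malformed Newick: unbalanced ')' at position ", which(bal < 0L)[1])
  }
  if (tail_val(bal) != 0L) stop("malformed Newick: unclosed '(' (", tail_val(bal),
                                " open at end of string)")
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr)) stop("malformed Newick string")
  phylo_to_bhv(tr, root_label)
}

tail_val <- function(x) x[length(x)]

fmt_len <- function(v) sprintf("%.17g", v)

#' Serialize a BHV tree to Newick
#'
#' The root leaf appears as the last child of the top-level multifurcation,
#' so `parse_newick(write_newick(x))` reproduces `x` exactly (up to child
#' ordering inside the string).
#'
#' @param x a `bhv_tree`.
#' @export
write_newick <- function(x) {
  n <- x$n
  full <- sum(bitwShiftL(1L, 0:(n - 1L)))
  pendant <- x$pendant
  pendant[is.na(pendant)] <- 0
  emit <- function(m) {
    inside <- x$splits[bitwAnd(x$splits, m) == x$splits & x$splits != m]
    maximal <- inside[vapply(inside, function(s) {
      !any(bitwAnd(inside, s) == s & inside != s)
    }, logical(1))]
    covered <- Reduce(bitwOr, as.list(maximal), 0L)
    loose <- mask_leaves(bitwAnd(m, bitwNot(covered)), n)
    parts <- character(0)
    for (s in maximal) {
      i <- match(s, x$splits)
      parts <- c(parts, paste0(emit(s), ":", fmt_len(x$lengths[i])))
    }
    for (lf in loose) {
      parts <- c(parts, paste0(x$labels[lf + 1L], ":", fmt_len(pendant[lf])))
    }
    paste0("(", paste(parts, collapse = ","), ")")
  }
  top <- emit(full)
  top <- substr(top, 2L, nchar(top) - 1L)
  paste0("(", top, ",", x$labels[1], ":", fmt_len(x$root_edge), ");")
}

#' Read trees from a file
#'
#' Plain files hold one Newick string per line; files whose content starts
#' with `#NEXUS` are read as a NEXUS trees block via ape.
#'
#' @param path file path.
#' @param root_label passed to [parse_newick()].
#' @return a list of `bhv_tree` objects.
#' @export
read_trees <- function(path, root_label = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) > 0 && grepl("^#NEXUS", lines[1], ignore.case = TRUE)) {
    trs <- ape::read.nexus(path)
    if (inherits(trs, "phylo")) trs <- list(trs)
    return(lapply(trs, phylo_to_bhv, root_label = root_label))
  }
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, parse_newick, root_label = root_label)
}

#' Write trees to a file, one Newick per line
#' @param trees a list of `bhv_tree` objects.
#' @param path file path.
#' @export
write_trees <- function(trees, path) {
  writeLines(vapply(trees, write_newick, character(1)), path)
}

#' Export trees as sparse split-length records
#'
#' One row per edge: tree id, the split as a sorted comma-separated leaf
#' list, and the branch length.  Pendant edges appear as singletons.
#'
#' @param trees list of `bhv_tree` objects.
#' @param path output TSV path; if `NULL`, the data frame is returned.
#' @export
export_splits_tsv <- function(trees, path = NULL) {
  rows <- list()
  for (i in seq_along(trees)) {
    x <- trees[[i]]
    for (j in seq_along(x$splits)) {
      lv <- mask_leaves(x$splits[j], x$n)
      rows[[length(rows) + 1L]] <- data.frame(
        tree_id = i, split = paste(x$labels[lv + 1L], collapse = ","),
        length = x$lengths[j], stringsAsFactors = FALSE)
    }
    for (lf in seq_len(x$n)) {
      rows[[length(rows) + 1L]] <- data.frame(
        tree_id = i, split = x$labels[lf + 1L], length = x$pendant[lf],
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  if (!is.null(path)) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(df)
  } else df
}
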