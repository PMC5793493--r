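# Independent brute-force oracle for the geodesic distance: minimize the
# support length formula over ALL ordered partitions (A, B) of the
# incompatible split sets that satisfy (i) the valid-path condition (every
# split of A^(i) compatible with every split of B^(j) for j < i) and
# (ii) the ratio ordering ||A^(1)||/||B^(1)|| <= ... <= ||A^(l)||/||B^(l)||.
# Both constraints are needed for the formula value to be the length of an
# achievable path: by Cauchy-Schwarz the formula always decreases under
# further splitting, so without (ii) the minimum would undercut the true
# geodesic (e.g. it would "shortcut" the kinked cone-path geodesic of the
# T5 example).  Exponential in the number of incompatible splits.

# all ways to partition the index vector `idx` into `l` ordered nonempty blocks
ordered_partitions <- function(idx, l) {
  n <- length(idx)
  if (l == 1) return(list(list(idx)))
  out <- list()
  # assign each element a block label 1..l such that all labels occur
  grid <- do.call(expand.grid, rep(list(seq_len(l)), n))
  for (r in seq_len(nrow(grid))) {
    lab <- as.integer(grid[r, ])
    if (length(unique(lab)) != l) next
    out[[length(out) + 1L]] <- lapply(seq_len(l), function(b) idx[lab == b])
  }
  out
}

brute_distance <- function(x, y, internal_only = TRUE) {
  px <- bhvpca:::pack_tree(x, internal_only)
  py <- bhvpca:::pack_tree(y, internal_only)
  xm <- px$mask; xl <- px$len; ym <- py$mask; yl <- py$len
  compat_all <- function(m, ms) all(vapply(ms, function(o) {
    bhvpca:::cpp_compat(m, o)
  }, logical(1)))
  cx <- vapply(xm, compat_all, logical(1), ms = as.list(ym))
  cy <- vapply(ym, compat_all, logical(1), ms = as.list(xm))
  # common contribution (shared or one-sided compatible splits)
  comm <- 0
  ylen_of <- function(m) { i <- match(m, ym); if (is.na(i)) 0 else yl[i] }
  xlen_of <- function(m) { i <- match(m, xm); if (is.na(i)) 0 else xl[i] }
  for (i in which(cx)) comm <- comm + (xl[i] - ylen_of(xm[i]))^2
  for (j in which(cy)) if (!(ym[j] %in% xm[cx])) comm <- comm + (yl[j] - xlen_of(ym[j]))^2
  ai <- which(!cx); bi <- which(!cy)
  if (length(ai) == 0) return(sqrt(comm))
  best <- Inf
  for (l in seq_len(min(length(ai), length(bi)))) {
    pa <- ordered_partitions(ai, l)
    pb <- ordered_partitions(bi, l)
    for (A in pa) for (B in pb) {
      ok <- TRUE
      for (i in seq_len(l)) {
        for (j in seq_len(i - 1L)) {
          for (a in A[[i]]) for (b in B[[j]]) {
            if (!bhvpca:::cpp_compat(xm[a], ym[b])) { ok <- FALSE; break }
          }
          if (!ok) break
        }
        if (!ok) break
      }
      if (!ok) next
      na <- vapply(A, function(b) sqrt(sum(xl[b]^2)), numeric(1))
      nb <- vapply(B, function(b) sqrt(sum(yl[b]^2)), numeric(1))
      ratios <- na / nb
      if (l > 1 && any(diff(ratios) < -1e-12)) next
      s <- sum((na + nb)^2)
      if (s < best) best <- s
    }
  }
  sqrt(best + comm)
}
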