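# Shared helpers: the T5 example's closed forms and a tree builder for its
# signed coordinates.

t5_flat <- function(p) c(p[1] - 2 * p[2] + p[3], p[1] + p[2] - 2 * p[3], 1 + p[1])

t5_curved <- function(p) {
  f <- (p[1] + p[2]) / (p[1] - 2 * p[2])
  c(p[1] - 2 * p[2] + p[3] * sqrt(5 / (1 + f^2)),
    p[1] + p[2] - p[3] * sqrt(5 / (1 + f^-2)),
    p[1] + 1)
}

t5_tree <- function(x1, x2, x3) {
  sp <- list(); ln <- c()
  if (x1 > 0) { sp <- c(sp, list(c(2, 3))); ln <- c(ln, x1) }
  if (x1 < 0) { sp <- c(sp, list(c(3, 4, 5))); ln <- c(ln, -x1) }
  if (x2 > 0) { sp <- c(sp, list(c(4, 5))); ln <- c(ln, x2) }
  if (x2 < 0) { sp <- c(sp, list(c(2, 3, 4))); ln <- c(ln, -x2) }
  sp <- c(sp, list(c(2, 3, 4, 5))); ln <- c(ln, x3)
  bhv_tree(sp, ln, 5)
}

n_incompatible <- function(s) {
  if (length(s$A) == 0) 0L else sum(vapply(s$A, function(b) length(b$mask), integer(1)))
}

rand_pair <- function(N) list(random_tree_gamma(N), random_tree_gamma(N))

validate_topology_tree <- function(x) {
  validate_topology(lapply(x$splits, bhvpca:::mask_leaves, n = x$n), x$n) &&
    all(x$lengths > 0)
}

# every SPR topology of a tree (internal-clade and leaf prunes)
all_spr_keys <- function(y) {
  ms <- function(m) bhvpca:::mask_size(m)
  full <- sum(bitwShiftL(1L, 0:(y$n - 1L)))
  out <- character(0)
  prunes <- c(y$splits, bitwShiftL(1L, 0:(y$n - 1L)))
  for (S in prunes) {
    rest <- bitwAnd(full, bitwNot(S))
    if (ms(rest) < 2) next
    sup <- y$splits[bitwAnd(y$splits, S) == S & y$splits != S]
    if (length(sup) == 0L && is.na(match(rest, y$splits))) next
    removed <- if (length(sup)) sup[which.min(vapply(sup, ms, integer(1)))] else rest
    cand <- integer(0)
    for (T in y$splits) {
      if (T == S || bitwAnd(T, S) == T || T == removed) next
      cand <- c(cand, if (bitwAnd(T, S) == 0L) T else bitwAnd(T, bitwNot(S)))
    }
    leaves_rest <- which(bitwAnd(bitwShiftR(rest, 0:(y$n - 1L)), 1L) == 1L)
    cand <- unique(c(cand, bitwShiftL(1L, leaves_rest - 1L)))
    cand <- cand[bitwAnd(cand, S) == 0L]
    for (U in cand) out <- c(out, topology_key(spr(y, S, U, as_mask = TRUE)))
    out <- c(out, topology_key(spr(y, S, "root", as_mask = TRUE)))
  }
  out
}
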