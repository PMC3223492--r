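# Independent brute-force oracles and small fixtures shared across tests.

# Exhaustive affine-gap global alignment score: enumerates every alignment
# recursively, charging gop + gep for the first position of each gap run and
# gep for extensions.  Exponential -- for tiny sequences only.
bf_global_score <- function(c1, c2, mat, gop, gep) {
  n1 <- length(c1)
  n2 <- length(c2)
  rec <- function(i, j, prev) {
    if (i > n1 && j > n2) return(0)
    best <- -Inf
    if (i <= n1 && j <= n2)
      best <- max(best, mat[c1[i], c2[j]] + rec(i + 1, j + 1, 0L))
    if (i <= n1)
      best <- max(best, -(if (prev == 1L) gep else gop + gep) + rec(i + 1, j, 1L))
    if (j <= n2)
      best <- max(best, -(if (prev == 2L) gep else gop + gep) + rec(i, j + 1, 2L))
    best
  }
  rec(1L, 1L, 0L)
}

# Local score as the definition states it: the best global score over every
# pair of (possibly empty) contiguous fragments, floored at zero.
bf_local_score <- function(c1, c2, mat, gop, gep) {
  best <- 0
  n1 <- length(c1)
  n2 <- length(c2)
  for (i1 in seq_len(n1)) for (i2 in i1:n1)
    for (j1 in seq_len(n2)) for (j2 in j1:n2)
      best <- max(best, bf_global_score(c1[i1:i2], c2[j1:j2], mat, gop, gep))
  best
}

# all sequences over a reduced residue set, by length
enum_seqs <- function(letters_idx, len) {
  if (len == 0) return(list(integer(0)))
  grids <- rep(list(letters_idx), len)
  g <- do.call(expand.grid, grids)
  lapply(seq_len(nrow(g)), function(r) as.integer(g[r, ]))
}

# a degenerate parameter set: no indels, no substitutions
frozen_params <- function(ancestor_length = 30)
  evol_params(30, ancestor_length = ancestor_length, indel_rate = 0, cycles = 0)

# construct a minimal test_pair by hand from origin maps (core-only, no consoles)
hand_pair <- function(k1, origin1, k2, origin2) {
  shared <- sort(intersect(origin1[!is.na(origin1)], origin2[!is.na(origin2)]))
  ref <- cbind(i = match(shared, origin1), j = match(shared, origin2))
  structure(list(
    s1 = k1, s2 = k2,
    core1 = c(start = 1L, end = nchar(k1)),
    core2 = c(start = 1L, end = nchar(k2)),
    reference = ref, ancestor = NA_character_,
    k1 = match(strsplit(k1, "")[[1]], aa_alphabet()),
    k2 = match(strsplit(k2, "")[[1]], aa_alphabet()),
    origin1 = origin1, origin2 = origin2, scheme = "diverging"),
    class = "test_pair")
}
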