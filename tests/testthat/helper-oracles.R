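# Independent oracles, implemented before (and apart from) the production
# dynamic programmes they check.

# Best local alignment score over an arbitrary pair-score matrix S under
# affine gaps (gap of length L costs go + L*ge), by exhaustive recursion
# over alignment operation sequences (with caching on the (i, j, last-op)
# state; the recursion may stop at any point, which is what makes it local).
oracle_local_matrix <- function(S, go, ge) {
  n <- nrow(S); m <- ncol(S)
  memo <- array(NA_real_, dim = c(n + 1, m + 1, 3))  # 1 = M/none, 2 = X, 3 = Y
  g <- function(i, j, prev) {
    v <- memo[i, j, prev]
    if (!is.na(v)) return(v)
    best <- 0  # stop here
    if (i <= n && j <= m) best <- max(best, S[i, j] + g(i + 1, j + 1, 1))
    if (i <= n) {
      cost <- if (prev == 2) ge else go + ge
      best <- max(best, -cost + g(i + 1, j, 2))
    }
    if (j <= m) {
      cost <- if (prev == 3) ge else go + ge
      best <- max(best, -cost + g(i, j + 1, 3))
    }
    memo[i, j, prev] <<- best
    best
  }
  best <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) best <- max(best, g(i, j, 1))
  best
}

oracle_local_score <- function(a, b, scheme) {
  ai <- b12screen:::encode_seq(a); bi <- b12screen:::encode_seq(b)
  oracle_local_matrix(scheme$matrix[ai, bi, drop = FALSE],
                      scheme$gap_open, scheme$gap_extend)
}

# random protein of length n over the 20 standard residues
rand_prot <- function(n) paste(sample(aa_alphabet()[1:20], n, TRUE), collapse = "")

# random tree with positive branch lengths and its (additive) path-length
# matrix
rand_additive <- function(n) {
  tr <- ape::rtree(n, br = function(k) runif(k, 0.1, 2))
  list(tree = tr, D = ape::cophenetic.phylo(tr))
}

# substitute a fraction of residues (never with the original residue)
mutate_prot <- function(s, p) {
  v <- strsplit(s, "")[[1]]
  hit <- runif(length(v)) < p
  v[hit] <- vapply(v[hit], function(r)
    sample(setdiff(aa_alphabet()[1:20], r), 1), "")
  paste(v, collapse = "")
}
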