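# Independent oracles and small generators used across the suite.

random_aa <- function(n) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
               n, replace = TRUE), collapse = "")
}

# Brute-force local alignment score: plain dynamic programme that prices a
# gap of length L as open + L * extend by enumerating every gap length
# explicitly (no affine three-state optimization). Quadratic per cell, only
# usable on short sequences; independent of the package's C++ kernel.
oracle_sw_score <- function(a, b, gap_open = 11, gap_extend = 1) {
  S <- fcptools::substitution_matrix("BLOSUM62")
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  H <- matrix(0, n + 1, m + 1)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      best <- 0
      cand <- H[i, j] + S[x[i], y[j]]
      if (cand > best) best <- cand
      for (L in seq_len(i - 1)) {          # gap in b ending at (i, j)
        cand <- H[i - L, j] + S[x[i], y[j]] - (gap_open + L * gap_extend)
        # gap must be followed by a match to stay in H terms; emulate by
        # allowing the gap directly before the (i, j) substitution
        if (cand > best) best <- cand
      }
      for (L in seq_len(j - 1)) {          # gap in a ending at (i, j)
        cand <- H[i, j - L] + S[x[i], y[j]] - (gap_open + L * gap_extend)
        if (cand > best) best <- cand
      }
      H[i + 1, j + 1] <- best
    }
  }
  max(H)
}

# second independent reference for local alignment scores
biostrings_sw_score <- function(a, b, gap_open = 11, gap_extend = 1) {
  s <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = "BLOSUM62", type = "local",
    gapOpening = gap_open, gapExtension = gap_extend, scoreOnly = TRUE)
  max(0, s)
}

# random additive distance matrix from a random tree with known topology
random_additive <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, br = function(k) runif(k, 0.1, 1))
  list(tree = tr, D = cophenetic(tr))
}

# unrooted topologies equal?
same_topology <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2)) == 0
}
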