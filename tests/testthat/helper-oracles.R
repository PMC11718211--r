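# shared fixtures and independent oracles used across the test files

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# mutate exactly n_mut positions (substitutions to a different base)
mutate_exact <- function(seq, n_mut) {
  v <- strsplit(seq, "")[[1]]
  at <- sample(length(v), n_mut)
  v[at] <- vapply(v[at], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                  character(1))
  paste(v, collapse = "")
}

# brute-force affine-gap local alignment score, O(nm), written independently
# of the package implementation; gap of length g costs gap_open + g * gap_ext
sw_bruteforce <- function(q, t, match = 1, mismatch = -2,
                          gap_open = -3, gap_ext = -1) {
  qv <- strsplit(q, "")[[1]]
  tv <- strsplit(t, "")[[1]]
  n <- length(qv); m <- length(tv)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)
  F <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in seq(2, n + 1)) {
    for (j in seq(2, m + 1)) {
      E[i, j] <- max(H[i, j - 1] + gap_open + gap_ext, E[i, j - 1] + gap_ext)
      F[i, j] <- max(H[i - 1, j] + gap_open + gap_ext, F[i - 1, j] + gap_ext)
      s <- if (qv[i - 1] == tv[j - 1]) match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# independent local-alignment score through Biostrings (same gap convention)
biostrings_sw_score <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  Biostrings::score(Biostrings::pairwiseAlignment(
    a, b, type = "local", substitutionMatrix = mat,
    gapOpening = 3, gapExtension = 1))
}

# two-sided Fisher exact p by explicit hypergeometric enumeration with
# choose(); tables with probability <= P(observed) (with the customary
# 1 + 1e-7 slack) are summed
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  xs <- max(0, c1 - r2):min(r1, c1)
  pr <- choose(r1, xs) * choose(r2, c1 - xs) / choose(n, c1)
  sum(pr[pr <= pr[xs == a] * (1 + 1e-7)])
}

# alignment table straight from piRNA simulator truth (error-free reads map
# to their planted footprints, so truth doubles as the mapped alignments)
truth_alignments <- function(truth, consensus_length, te = "te") {
  aln <- truth[, c("read_id", "strand", "start", "width", "five_prime")]
  aln$weight <- rep(1, nrow(aln))
  attr(aln, "consensus_length") <- consensus_length
  attr(aln, "te") <- te
  aln
}

# small LTR element: two identical terminal repeats around a random core
make_ltr_te <- function(name = "toyTE", ltr_len = 300, core_len = 1400) {
  ltr <- rand_seq(ltr_len)
  te_consensus(name, paste0(ltr, rand_seq(core_len), ltr))
}
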