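## Independent reference implementations used as oracles.  These are kept
## deliberately naive and separate from the package code paths they check.

## N50 by direct definition: the largest length L in the multiset such
## that components of length >= L sum to at least half the total.
n50_oracle <- function(lengths) {
  total <- sum(as.numeric(lengths))
  cand <- sort(unique(lengths), decreasing = TRUE)
  for (L in cand)
    if (sum(as.numeric(lengths[lengths >= L])) >= total / 2) return(L)
  min(lengths)
}

## Needleman-Wunsch score with affine gaps (gap of length L costs
## open + extend * L) and free end gaps, as a plain three-matrix DP.
nw_score_oracle <- function(a, b, mat, open = 10, extend = 0.5) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B); NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)
  Iy <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  Ix[seq_len(n) + 1, 1] <- 0  # leading gap in b: free
  Iy[1, seq_len(m) + 1] <- 0  # leading gap in a: free
  for (i in seq_len(n)) for (j in seq_len(m)) {
    M[i + 1, j + 1] <- mat[A[i], B[j]] + max(M[i, j], Ix[i, j], Iy[i, j])
    Ix[i + 1, j + 1] <- max(M[i, j + 1] - open - extend,
                            Ix[i, j + 1] - extend)
    Iy[i + 1, j + 1] <- max(M[i + 1, j] - open - extend,
                            Iy[i + 1, j] - extend)
  }
  V <- pmax(M, Ix, Iy)
  max(V[, m + 1], V[n + 1, ])  # free trailing gaps
}

blosum62_test <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

random_protein <- function(len) {
  paste(sample(rownames(blosum62_test)[1:20], len, replace = TRUE),
        collapse = "")
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

rc <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

## undirected adjacency pairs of an ordered scaffold list
adjacency_pairs <- function(d, poscol) {
  d <- d[order(d[[poscol]]), , drop = FALSE]
  if (nrow(d) < 2L) return(character(0))
  paste(pmin(d$scaffold_id[-nrow(d)], d$scaffold_id[-1]),
        pmax(d$scaffold_id[-nrow(d)], d$scaffold_id[-1]))
}
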