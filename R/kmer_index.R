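## k-mer encoding: A,C,G,T -> 0..3; anything else (N) -> NA so that any
## k-mer overlapping an ambiguous base drops out of the index.

base_codes <- function(s) {
  x <- utf8ToInt(s)
  v <- rep(NA_real_, length(x))
  v[x == 65L] <- 0  # A
  v[x == 67L] <- 1  # C
  v[x == 71L] <- 2  # G
  v[x == 84L] <- 3  # T
  v
}

## numeric 4^k encoding of every k-mer start position (NA where invalid);
## exact in doubles for k <= 26
kmer_codes <- function(s, k) {
  v <- base_codes(s)
  n <- length(v) - k + 1L
  if (n < 1L) return(numeric(0))
  acc <- numeric(n)
  for (i in seq_len(k)) acc <- acc * 4 + v[i:(n + i - 1L)]
  acc
}

#' Build a k-mer index over a scaffold set
#'
#' Indexes every forward-strand k-mer position of every scaffold.  Queries
#' are searched on both strands by also scanning their reverse complement,
#' so minus-strand hits are found without doubling the index.
#'
#' @param scaffolds named character vector or [Biostrings::DNAStringSet].
#' @param k k-mer size (8..26); must not exceed the shortest query you
#'   intend to map.
#' @return an object of class `kmer_index` holding the postings table and
#'   the scaffold sequences.
#' @export
build_index <- function(scaffolds, k = 15L) {
  k <- as.integer(k)
  if (k < 8L || k > 26L) stop("k must be between 8 and 26")
  seqs <- as_seq_vector(scaffolds)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("scaffolds must be named")
  tabs <- lapply(seq_along(seqs), function(i) {
    codes <- kmer_codes(seqs[[i]], k)
    keep <- which(!is.na(codes))
    if (!length(keep)) return(NULL)
    data.table::data.table(kmer = codes[keep], sid = i, tpos = keep)
  })
  postings <- data.table::rbindlist(tabs)
  if (nrow(postings)) data.table::setkey(postings, kmer)
  structure(list(k = k, postings = postings, seqs = seqs,
                 lengths = nchar(seqs)),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat("kmer_index: k=", x$k, ", ", length(x$seqs), " sequences, ",
      nrow(x$postings), " postings\n", sep = "")
  invisible(x)
}
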