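#' Compute contig and scaffold assembly statistics
#'
#' Contigs are maximal runs of non-gap sequence inside each scaffold; a
#' gap is a run of at least `gap_min_n` consecutive `N`s.  N50 is the
#' largest length `L` such that components of length >= `L` together
#' contain at least half of the total component bases.
#'
#' @param records scaffolds as a named character vector or
#'   [Biostrings::DNAStringSet].
#' @param gap_min_n minimum N-run length that splits a scaffold into
#'   contigs (default 1: any N is a gap).
#' @return an object of class `assembly_stats`: list with `n_contigs`,
#'   `total_bp`, `max_contig`, `mean_contig`, `contig_n50`,
#'   `scaffold_n50`, and the raw `contig_lengths`.
#' @export
compute_assembly_stats <- function(records, gap_min_n = 1L) {
  seqs <- as_seq_vector(records)
  if (length(seqs) == 0L) stop("no records")
  pat <- sprintf("N{%d,}", gap_min_n)
  contig_lengths <- unlist(lapply(seqs, function(s) {
    parts <- strsplit(s, pat)[[1]]
    nchar(parts[nzchar(parts)])
  }), use.names = FALSE)
  if (length(contig_lengths) == 0L) stop("records contain no non-gap sequence")
  structure(list(
    n_contigs = length(contig_lengths),
    total_bp = sum(contig_lengths),
    max_contig = max(contig_lengths),
    mean_contig = mean(contig_lengths),
    contig_n50 = n50(contig_lengths),
    scaffold_n50 = n50(nchar(seqs)),
    contig_lengths = contig_lengths
  ), class = "assembly_stats")
}

#' Weighted-median (N50) component size
#'
#' @param lengths integer vector of component lengths.
#' @return the N50 length.
#' @export
n50 <- function(lengths) {
  lengths <- sort(unname(lengths), decreasing = TRUE)
  lengths[which(cumsum(as.numeric(lengths)) >= sum(as.numeric(lengths)) / 2)[1L]]
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat(sprintf(paste0("assembly: %d contigs, %s bp total, max %s, ",
                     "mean %s, contig N50 %s, scaffold N50 %s\n"),
              x$n_contigs, format(x$total_bp, big.mark = ","),
              format(x$max_contig, big.mark = ","),
              format(round(x$mean_contig), big.mark = ","),
              format(x$contig_n50, big.mark = ","),
              format(x$scaffold_n50, big.mark = ",")))
  invisible(x)
}
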