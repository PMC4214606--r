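#' Contamination-filter policy for mRNA reads
#'
#' A read is kept only when its best alignment length against the
#' transcript set strictly exceeds the threshold for its read length.
#' The stated thresholds are 70 bp for 76-bp reads and 90 bp for 100-bp
#' reads; lengths not listed fall back to `floor(fallback_fraction *
#' read_length)` (0.90, interpolating the two stated ratios).
#'
#' @param thresholds named numeric vector mapping read length to the
#'   maximum alignment length that is still filtered out.
#' @param fallback_fraction fraction of the read length used for unlisted
#'   read lengths.
#' @param paired whether mate synchronization applies.
#' @return a `filter_policy` list.
#' @export
filter_policy <- function(thresholds = c("76" = 70, "100" = 90),
                          fallback_fraction = 0.90, paired = FALSE) {
  rl <- as.numeric(names(thresholds))
  if (any(thresholds >= rl))
    stop("every threshold must be smaller than its read length")
  if (fallback_fraction <= 0 || fallback_fraction >= 1)
    stop("fallback_fraction must be in (0,1)")
  structure(list(thresholds = thresholds,
                 fallback_fraction = fallback_fraction, paired = paired),
            class = "filter_policy")
}

filter_threshold <- function(read_length, policy) {
  key <- as.character(read_length)
  known <- match(key, names(policy$thresholds))
  ifelse(!is.na(known), policy$thresholds[known],
         floor(policy$fallback_fraction * read_length))
}

#' Filter reads for genomic contamination by best alignment length
#'
#' @param reads a [Biostrings::QualityScaledDNAStringSet] (see
#'   [read_fastq()]) or named character vector.
#' @param aln_lengths best alignment length per read: either a named
#'   numeric vector or a hits data.frame ([read_aln_table()] /
#'   [map_sequences()]), in which case the best hit per read is used.
#'   Reads without an alignment count as length 0.
#' @param policy a [filter_policy()].
#' @return list with `keep` (named logical per read, after mate
#'   synchronization when `policy$paired`), and `summary`
#'   (`n_input, n_kept, n_removed`).
#' @export
filter_reads <- function(reads, aln_lengths, policy = filter_policy()) {
  ids <- names(reads)
  if (is.null(ids)) stop("reads must be named")
  if (is.data.frame(aln_lengths)) {
    best <- best_hits(aln_lengths)
    aln_lengths <- stats::setNames(best$aln_len, best$query_id)
  }
  orphans <- setdiff(names(aln_lengths), ids)
  if (length(orphans))
    stop("alignment ids not present in the read set: ",
         paste(utils::head(orphans, 5L), collapse = ", "))
  alen <- aln_lengths[ids]
  alen[is.na(alen)] <- 0
  rl <- if (is.character(reads)) nchar(reads) else width(reads)
  keep <- stats::setNames(alen > filter_threshold(rl, policy), ids)
  if (policy$paired) keep <- synchronize_pairs(keep)
  list(keep = keep,
       summary = list(n_input = length(keep), n_kept = sum(keep),
                      n_removed = sum(!keep)))
}

#' Synchronize keep/remove decisions across mate pairs
#'
#' A pair survives only when both mates survive.  Pairing is derived from
#' read ids by stripping a `/1`/`/2` (or `_1`/`_2`) suffix; ids without a
#' partner raise an error.
#'
#' @param keep named logical vector of per-read decisions.
#' @param pairing optional data.frame `id1, id2`; derived from ids when
#'   omitted.
#' @return adjusted named logical vector.
#' @export
synchronize_pairs <- function(keep, pairing = NULL) {
  ids <- names(keep)
  if (is.null(pairing)) {
    base <- sub("[/_][12]$", "", ids)
    tab <- table(base)
    bad <- names(tab)[tab != 2L]
    if (length(bad))
      stop("unpaired read id(s) in paired mode: ",
           paste(utils::head(bad, 5L), collapse = ", "))
    ok <- stats::ave(as.integer(keep), base, FUN = min) == 1L
    return(stats::setNames(as.logical(ok), ids))
  }
  for (i in seq_len(nrow(pairing))) {
    pairik <- keep[[pairing$id1[i]]] && keep[[pairing$id2[i]]]
    keep[[pairing$id1[i]]] <- pairik
    keep[[pairing$id2[i]]] <- pairik
  }
  keep
}

#' File-level contamination filter for FASTQ input
#'
#' Reads one (single-end) or two (paired-end) FASTQ files, applies
#' [filter_reads()], and writes the kept reads back out, preserving order
#' and pairing.
#'
#' @param fastq_in character vector of 1 or 2 input paths.
#' @param aln_lengths as in [filter_reads()]; for paired data ids must
#'   carry `/1`/`/2` suffixes.
#' @param fastq_out output paths (same length as `fastq_in`).
#' @param policy a [filter_policy()]; `paired` is inferred from the
#'   number of files.
#' @return the filter summary, invisibly.
#' @export
filter_fastq <- function(fastq_in, aln_lengths, fastq_out,
                         policy = filter_policy()) {
  stopifnot(length(fastq_in) %in% c(1L, 2L),
            length(fastq_out) == length(fastq_in))
  paired <- length(fastq_in) == 2L
  sets <- lapply(fastq_in, read_fastq)
  if (paired) {
    if (length(sets[[1]]) != length(sets[[2]]))
      stop("mate files differ in read count")
    for (i in 1:2)
      if (!all(grepl("[/_][12]$", names(sets[[i]]))))
        names(sets[[i]]) <- paste0(names(sets[[i]]), "/", i)
  }
  all_reads <- if (paired) c(sets[[1]], sets[[2]]) else sets[[1]]
  policy$paired <- paired
  res <- filter_reads(all_reads, aln_lengths, policy)
  for (i in seq_along(sets)) {
    keep_i <- res$keep[names(sets[[i]])]
    write_fastq(suppressWarnings(sets[[i]][keep_i]), fastq_out[i])
  }
  invisible(res$summary)
}
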