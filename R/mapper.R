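#' Map query sequences onto an indexed scaffold set
#'
#' Seed-and-extend placement: exact k-mer seeds are collected on both
#' strands, chained by diagonal (ungapped, so colinear seeds share one
#' diagonal), and each chained candidate is scored by direct base
#' comparison of the full overlap between query and scaffold.  Hits below
#' `min_identity` percent or covering less than `min_cov` of the query are
#' dropped.  The mapper is ungapped by design: it recovers loci,
#' orientation and identity for ordering decisions; indel-containing
#' alignments should be imported from an external aligner table instead
#' (see [read_aln_table()]).
#'
#' @param queries named character vector or [Biostrings::XStringSet] of
#'   DNA queries.
#' @param index a [build_index()] object.
#' @param min_identity minimum percent identity of a reported hit.
#' @param min_cov minimum fraction of the query covered by the alignment.
#' @param min_seeds minimum number of colinear seeds required to evaluate
#'   a candidate (queries shorter than `2k` need only one).
#' @return hits data.frame in the layout of [read_aln_table()]; minus
#'   strand is encoded by `t_start > t_end` and flagged in `strand`.
#'   Within each query, hits are sorted by score (descending).
#' @export
map_sequences <- function(queries, index, min_identity = 95,
                          min_cov = 0.5, min_seeds = 2L) {
  stopifnot(inherits(index, "kmer_index"))
  qs <- as_seq_vector(queries)
  if (length(qs) == 0L || nrow(index$postings) == 0L) return(empty_hits())
  if (is.null(names(qs))) names(qs) <- paste0("q", seq_along(qs))
  k <- index$k
  qlen <- nchar(qs)

  cands <- list()
  for (str in c("+", "-")) {
    oriented <- if (str == "+") qs else revcomp(qs)
    qtabs <- lapply(seq_along(oriented), function(i) {
      codes <- kmer_codes(oriented[[i]], k)
      keep <- which(!is.na(codes))
      if (!length(keep)) return(NULL)
      data.table::data.table(kmer = codes[keep], qid = i, qpos = keep)
    })
    qk <- data.table::rbindlist(qtabs)
    if (nrow(qk) == 0L) next
    hits <- index$postings[qk, on = "kmer", nomatch = NULL,
                           allow.cartesian = TRUE]
    if (nrow(hits) == 0L) next
    hits[, diag := tpos - qpos]
    grp <- hits[, list(nseed = .N), by = c("qid", "sid", "diag")]
    grp[, strand := str]
    cands[[str]] <- grp
  }
  cand <- data.table::rbindlist(cands)
  if (is.null(cand) || nrow(cand) == 0L) return(empty_hits())

  need <- ifelse(qlen[cand$qid] < 2L * k, 1L, min_seeds)
  cand <- cand[cand$nseed >= need, ]
  if (nrow(cand) == 0L) return(empty_hits())

  out <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    qi <- cand$qid[i]; si <- cand$sid[i]; dg <- cand$diag[i]
    ql <- qlen[qi]; sl <- index$lengths[si]
    t_lo <- max(1L, dg + 1L); t_hi <- min(sl, dg + ql)
    aln_len <- t_hi - t_lo + 1L
    if (aln_len < min_cov * ql) next
    q_lo <- t_lo - dg; q_hi <- t_hi - dg
    oq <- if (cand$strand[i] == "+") qs[[qi]] else revcomp(qs[[qi]])
    a <- utf8ToInt(substr(oq, q_lo, q_hi))
    b <- utf8ToInt(substr(index$seqs[[si]], t_lo, t_hi))
    matches <- sum(a == b)
    identity <- 100 * matches / aln_len
    if (identity < min_identity) next
    minus <- cand$strand[i] == "-"
    out[[i]] <- data.frame(
      query_id = names(qs)[qi], target_id = names(index$seqs)[si],
      identity = identity, aln_len = aln_len,
      mismatches = aln_len - matches, gap_opens = 0L,
      q_start = if (minus) ql - q_hi + 1L else q_lo,
      q_end = if (minus) ql - q_lo + 1L else q_hi,
      t_start = if (minus) t_hi else t_lo,
      t_end = if (minus) t_lo else t_hi,
      evalue = NA_real_, score = 2 * matches - 3 * (aln_len - matches),
      strand = cand$strand[i], matches = matches,
      t_lo = t_lo, t_hi = t_hi, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) return(empty_hits())
  res[order(match(res$query_id, names(qs)), -res$score,
            -res$identity, res$target_id), , drop = FALSE]
}

#' Map a single query sequence
#'
#' @param query one DNA sequence (length-1 character or [Biostrings::DNAString]).
#' @param ... passed to [map_sequences()].
#' @inheritParams map_sequences
#' @return hits data.frame (possibly empty), sorted by score descending.
#' @export
map_sequence <- function(query, index, ...) {
  if (methods::is(query, "DNAString")) query <- as.character(query)
  q <- stats::setNames(as_seq_vector(query)[1L],
                       if (is.null(names(query))) "query" else names(query)[1L])
  map_sequences(q, index, ...)
}

#' Best alignment per query (single-target policy)
#'
#' Highest score wins; ties are broken by higher identity, longer
#' alignment, then lexicographically smallest target id.  This mirrors the
#' single-best-alignment reporting policy of `-max_target_seqs 1`.
#'
#' @param hits hits data.frame for one query.
#' @return a one-row data.frame, or `NULL` when `hits` is empty.
#' @export
best_hit <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0L) return(NULL)
  o <- order(-hits$score, -hits$identity, -hits$aln_len, hits$target_id)
  hits[o[1L], , drop = FALSE]
}

## vectorized best_hit: one row per query_id present
best_hits <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0L) return(empty_hits())
  o <- order(hits$query_id, -hits$score, -hits$identity, -hits$aln_len,
             hits$target_id)
  h <- hits[o, , drop = FALSE]
  h[!duplicated(h$query_id), , drop = FALSE]
}

#' Read ortholog exon metadata
#'
#' The metadata TSV carries, for every reference exon sequence, its parent
#' gene, its order along the transcript and its location on the reference
#' genome.  Columns: `exon_id, gene_id, exon_index, ref_chrom, ref_start,
#' ref_end, ref_strand`.
#'
#' @param path path to the TSV.
#' @return validated data.frame.
#' @export
read_exon_metadata <- function(path) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("exon_id", "gene_id", "exon_index", "ref_chrom",
            "ref_start", "ref_end", "ref_strand")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("exon metadata '", path, "': missing columns ",
         paste(miss, collapse = ", "))
  validate_exon_metadata(meta)
}

validate_exon_metadata <- function(meta) {
  for (g in unique(meta$gene_id)) {
    idx <- sort(meta$exon_index[meta$gene_id == g])
    if (!identical(as.integer(idx), seq_along(idx)))
      stop("exon metadata: gene '", g,
           "' exon_index values are not contiguous from 1")
  }
  if (anyDuplicated(meta$exon_id)) stop("exon metadata: duplicate exon_id")
  meta
}

#' Place reference exons on scaffolds
#'
#' Produces one evidence row per reference exon: its best placement (or
#' none) on the scaffold set, joined with the reference-side metadata that
#' the contiguity rule and synteny placement consume.  Alignments either
#' come from the internal mapper (`index`) or from an imported alignment
#' table (`external_table`), e.g. BLASTn outfmt-6.
#'
#' @param exon_records named exon sequences (transcript orientation);
#'   ignored when `external_table` is given.
#' @param gene_metadata data.frame from [read_exon_metadata()].
#' @param index a [build_index()] object (internal mapping path).
#' @param external_table hits data.frame from [read_aln_table()].
#' @param min_identity,min_cov filters for the internal mapper.
#' @return evidence data.frame, one row per metadata exon, with placement
#'   columns `mapped, target_id, t_lo, t_hi, strand, identity, score`.
#' @export
map_exons <- function(exon_records = NULL, gene_metadata, index = NULL,
                      external_table = NULL, min_identity = 95,
                      min_cov = 0.5) {
  meta <- validate_exon_metadata(gene_metadata)
  if (is.null(external_table)) {
    if (is.null(index) || is.null(exon_records))
      stop("supply either an index plus exon records, or an external table")
    qs <- as_seq_vector(exon_records)
    unknown <- setdiff(names(qs), meta$exon_id)
    if (length(unknown))
      stop("exon id '", unknown[1L], "' not present in metadata")
    hits <- map_sequences(qs, index, min_identity = min_identity,
                          min_cov = min_cov)
  } else {
    hits <- external_table
    hits <- hits[hits$query_id %in% meta$exon_id, , drop = FALSE]
  }
  best <- best_hits(hits)
  i <- match(meta$exon_id, best$query_id)
  ev <- data.frame(
    meta,
    ref_pos = (meta$ref_start + meta$ref_end) %/% 2L,
    mapped = !is.na(i),
    target_id = best$target_id[i],
    t_lo = best$t_lo[i], t_hi = best$t_hi[i],
    t_start = best$t_start[i], t_end = best$t_end[i],
    strand = best$strand[i],
    identity = best$identity[i], aln_len = best$aln_len[i],
    score = best$score[i],
    stringsAsFactors = FALSE
  )
  ev[order(ev$gene_id, ev$exon_index), , drop = FALSE]
}

#' Fraction of reads that map to an assembly
#'
#' @param reads named character vector, [Biostrings::DNAStringSet] or
#'   [Biostrings::QualityScaledDNAStringSet].
#' @param index a [build_index()] over the assembly.
#' @param min_identity,min_cov acceptance filters per read.
#' @return percent (0..100) of reads with at least one passing hit.
#' @export
assess_mappability <- function(reads, index, min_identity = 90,
                               min_cov = 0.9) {
  qs <- as_seq_vector(reads)
  if (length(qs) == 0L) stop("mappability is undefined for an empty read set")
  if (is.null(names(qs))) names(qs) <- paste0("read", seq_along(qs))
  hits <- map_sequences(qs, index, min_identity = min_identity,
                        min_cov = min_cov)
  100 * length(unique(hits$query_id)) / length(qs)
}
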