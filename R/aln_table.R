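#' Read a 12-column tabular alignment file (BLAST outfmt-6 dialect)
#'
#' Columns are `qseqid sseqid pident length mismatch gapopen qstart qend
#' sstart send evalue bitscore`.  Rows with `sstart > send` encode
#' minus-strand alignments (the outfmt-6 convention); a `strand` column and
#' orientation-free `t_lo`/`t_hi` columns are added for internal use.
#'
#' @param path path to the tab-separated table.
#' @param dialect only `"outfmt6"` is supported.
#' @return a data.frame of alignment hits (one row per HSP) with columns
#'   `query_id, target_id, identity, aln_len, mismatches, gap_opens,
#'   q_start, q_end, t_start, t_end, evalue, score, strand, matches,
#'   t_lo, t_hi`.
#' @export
read_aln_table <- function(path, dialect = "outfmt6") {
  if (!identical(dialect, "outfmt6"))
    stop("unknown alignment dialect '", dialect, "'")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_hits())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L))
    stop("alignment table '", path, "': expected 12 columns, got ",
         nf[which(nf != 12L)[1L]], " at line ", which(nf != 12L)[1L],
         call. = FALSE)
  m <- matrix(unlist(fields), ncol = 12L, byrow = TRUE)
  hits <- data.frame(
    query_id  = m[, 1L], target_id = m[, 2L],
    identity  = as.numeric(m[, 3L]), aln_len = as.integer(m[, 4L]),
    mismatches = as.integer(m[, 5L]), gap_opens = as.integer(m[, 6L]),
    q_start = as.integer(m[, 7L]), q_end = as.integer(m[, 8L]),
    t_start = as.integer(m[, 9L]), t_end = as.integer(m[, 10L]),
    evalue = as.numeric(m[, 11L]), score = as.numeric(m[, 12L]),
    stringsAsFactors = FALSE
  )
  hits$strand <- ifelse(hits$t_start > hits$t_end, "-", "+")
  hits$matches <- as.integer(round(hits$identity * hits$aln_len / 100))
  hits$t_lo <- pmin(hits$t_start, hits$t_end)
  hits$t_hi <- pmax(hits$t_start, hits$t_end)
  bad <- hits$q_start > hits$q_end
  if (any(bad))
    stop("alignment table '", path, "': q_start > q_end at line ",
         which(bad)[1L], call. = FALSE)
  hits
}

#' Write alignment hits as an outfmt-6 table
#'
#' @param hits a hits data.frame as returned by [read_aln_table()] or
#'   [map_sequence()].
#' @param path output path.
#' @export
write_aln_table <- function(hits, path) {
  out <- data.frame(hits$query_id, hits$target_id,
                    sprintf("%.2f", hits$identity), hits$aln_len,
                    hits$mismatches,
                    if (is.null(hits$gap_opens)) 0L else hits$gap_opens,
                    hits$q_start, hits$q_end, hits$t_start, hits$t_end,
                    if (is.null(hits$evalue)) 0
                    else ifelse(is.na(hits$evalue), 0, hits$evalue),
                    hits$score)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

empty_hits <- function() {
  data.frame(query_id = character(), target_id = character(),
             identity = numeric(), aln_len = integer(),
             mismatches = integer(), gap_opens = integer(),
             q_start = integer(), q_end = integer(),
             t_start = integer(), t_end = integer(),
             evalue = numeric(), score = numeric(),
             strand = character(), matches = integer(),
             t_lo = integer(), t_hi = integer(),
             stringsAsFactors = FALSE)
}
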