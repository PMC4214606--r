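#' Build an AGP from a chromosome table
#'
#' Component (`W`) rows alternate with fixed-length scaffold gap (`N`)
#' rows; the gap convention is `gap_type=scaffold`, `linkage=no`.
#'
#' @param chrom_table data.frame `chrom, position, scaffold_id,
#'   orientation` from [merge_placements()].
#' @param scaffold_lengths named integer vector (bp per scaffold).
#' @param gap_length N-gap placed between consecutive scaffolds.
#' @param object_prefix prefix for object names (default `"chr"`).
#' @return AGP data.frame (see [read_agp()]).
#' @export
build_agp <- function(chrom_table, scaffold_lengths, gap_length = 100L,
                      object_prefix = "chr") {
  miss <- setdiff(chrom_table$scaffold_id, names(scaffold_lengths))
  if (length(miss))
    stop("missing scaffold length for '", miss[1L], "'")
  rows <- list()
  for (ch in unique(chrom_table$chrom)) {
    d <- chrom_table[chrom_table$chrom == ch, , drop = FALSE]
    d <- d[order(d$position), , drop = FALSE]
    obj <- paste0(object_prefix, ch)
    at <- 0L; part <- 0L
    for (i in seq_len(nrow(d))) {
      if (i > 1L) {
        part <- part + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          object = obj, object_beg = at + 1L, object_end = at + gap_length,
          part_number = part, component_type = "N",
          component_id = NA_character_, component_beg = NA_integer_,
          component_end = NA_integer_, orientation = NA_character_,
          gap_length = gap_length, gap_type = "scaffold", linkage = "no",
          stringsAsFactors = FALSE)
        at <- at + gap_length
      }
      len <- scaffold_lengths[[d$scaffold_id[i]]]
      part <- part + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        object = obj, object_beg = at + 1L, object_end = at + len,
        part_number = part, component_type = "W",
        component_id = d$scaffold_id[i], component_beg = 1L,
        component_end = len, orientation = d$orientation[i],
        gap_length = NA_integer_, gap_type = NA_character_,
        linkage = NA_character_, stringsAsFactors = FALSE)
      at <- at + len
    }
  }
  agp <- do.call(rbind, rows)
  validate_agp(agp)
}

#' Assemble chromosome sequences from an AGP
#'
#' Minus-orientation components are reverse-complemented; gap rows become
#' runs of `N`.
#'
#' @param agp AGP data.frame ([build_agp()] or [read_agp()]).
#' @param scaffolds named character vector or [Biostrings::DNAStringSet]
#'   of component sequences.
#' @return named character vector of object (chromosome) sequences.
#' @export
build_chromosomes <- function(agp, scaffolds) {
  seqs <- as_seq_vector(scaffolds)
  out <- vapply(unique(agp$object), function(obj) {
    d <- agp[agp$object == obj, , drop = FALSE]
    d <- d[order(d$part_number), , drop = FALSE]
    pieces <- vapply(seq_len(nrow(d)), function(i) {
      if (d$component_type[i] == "N")
        return(strrep("N", d$gap_length[i]))
      cid <- d$component_id[i]
      if (!cid %in% names(seqs))
        stop("AGP component '", cid, "' has no sequence")
      s <- substr(seqs[[cid]], d$component_beg[i], d$component_end[i])
      if (d$orientation[i] == "-") revcomp(s) else s
    }, character(1))
    paste(pieces, collapse = "")
  }, character(1))
  names(out) <- unique(agp$object)
  bad <- which(nchar(out) !=
               vapply(unique(agp$object), function(o)
                 max(agp$object_end[agp$object == o]), numeric(1)))
  if (length(bad))
    stop("assembled length mismatch for object '",
         unique(agp$object)[bad[1L]], "'")
  out
}
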