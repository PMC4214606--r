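#' Curate scaffolds: detect chimeras and break them
#'
#' Runs the contiguity stage end to end: index the scaffolds, place the
#' reference exons, vote chromosomes per gene through the synteny table,
#' detect chimeric scaffolds, propose breakpoints and apply them.
#'
#' @param scaffolds named character vector or [Biostrings::DNAStringSet].
#' @param exon_records named exon sequences (transcript orientation).
#' @param exon_meta exon metadata ([read_exon_metadata()]).
#' @param synteny synteny blocks ([read_synteny()]).
#' @param k,min_identity,min_cov mapper settings.
#' @param min_run_genes cluster support threshold ([detect_chimeras()]).
#' @return list with `scaffolds` (post-break), `provenance`, `breakpoints`,
#'   `violations`, `chimeras` (cluster list), `evidence` (pre-break).
#' @export
curate_scaffolds <- function(scaffolds, exon_records, exon_meta, synteny,
                             k = 15L, min_identity = 95, min_cov = 0.5,
                             min_run_genes = 2L) {
  seqs <- as_seq_vector(scaffolds)
  idx <- build_index(seqs, k = k)
  evidence <- map_exons(exon_records, exon_meta, idx,
                        min_identity = min_identity, min_cov = min_cov)
  votes <- gene_chromosome_votes(exon_meta, synteny)
  violations <- detect_violations(evidence)
  chim <- detect_chimeras(evidence, votes, min_run_genes = min_run_genes)
  bps <- lapply(names(chim$clusters), function(s)
    propose_breakpoints(chim$clusters[[s]], seqs[[s]], s))
  bps <- if (length(bps)) do.call(rbind, bps)
    else data.frame(scaffold_id = character(), coordinate = integer(),
                    reason = character(), evidence_left = character(),
                    evidence_right = character(), stringsAsFactors = FALSE)
  br <- apply_breaks(seqs, bps)
  list(scaffolds = br$scaffolds, provenance = br$provenance,
       breakpoints = bps, violations = violations,
       chimeras = chim, evidence = evidence)
}

#' Place curated scaffolds on chromosomes
#'
#' Applies the three evidence tiers in order -- markers, synteny +
#' ortholog positions, reference tiling -- each tier only to scaffolds the
#' previous tiers left unplaced, then merges the decisions into a
#' chromosome table and builds AGP and chromosome sequences.
#'
#' @param scaffolds named character vector (post-curation).
#' @param exon_records,exon_meta,synteny comparative evidence inputs.
#' @param markers optional marker table ([read_markers()]); `NULL`
#'   disables tier 1.
#' @param reference optional named character vector of reference
#'   chromosomes; `NULL` disables tier 3.
#' @param override optional curation override table
#'   (see [merge_placements()]).
#' @param gap_length AGP inter-scaffold gap.
#' @param tiling_segment_bp tier-3 segment size.
#' @param k,min_identity,min_cov mapper settings.
#' @return list with `table`, `unplaced`, `decisions`, `agp`,
#'   `chromosomes` (named character), `evidence`.
#' @export
place_scaffolds <- function(scaffolds, exon_records, exon_meta, synteny,
                            markers = NULL, reference = NULL,
                            override = NULL, gap_length = 100L,
                            tiling_segment_bp = 10000L, k = 15L,
                            min_identity = 95, min_cov = 0.5) {
  seqs <- as_seq_vector(scaffolds)
  idx <- build_index(seqs, k = k)
  evidence <- map_exons(exon_records, exon_meta, idx,
                        min_identity = min_identity, min_cov = min_cov)
  decisions <- list()
  placed <- character(0)
  if (!is.null(markers) && nrow(markers)) {
    d1 <- place_by_markers(markers, idx)
    decisions$tier1 <- d1
    placed <- d1$scaffold_id[d1$placed]
  }
  rest <- setdiff(names(seqs), placed)
  if (length(rest)) {
    d2 <- place_by_synteny(rest, evidence, synteny)
    decisions$tier2 <- d2
    placed <- c(placed, d2$scaffold_id[d2$placed])
  }
  rest <- setdiff(names(seqs), placed)
  if (length(rest) && !is.null(reference)) {
    d3 <- place_by_tiling(seqs[rest], reference, synteny,
                          tiling_segment_bp = tiling_segment_bp, k = k)
    decisions$tier3 <- d3
  }
  merged <- merge_placements(do.call(rbind, decisions), override = override,
                             all_scaffolds = names(seqs))
  agp <- if (nrow(merged$table))
    build_agp(merged$table, nchar(seqs), gap_length = gap_length) else NULL
  chroms <- if (!is.null(agp)) build_chromosomes(agp, seqs) else character(0)
  list(table = merged$table, unplaced = merged$unplaced,
       decisions = do.call(rbind, decisions), agp = agp,
       chromosomes = chroms, evidence = evidence)
}

#' Run curation and placement on a simulated world
#'
#' Convenience wrapper used by the examples and the acceptance checks:
#' curates the world's scaffolds, then places the post-break scaffold set.
#'
#' @param world a [simulate_world()] result.
#' @param use_markers include tier-1 marker evidence.
#' @param use_tiling include tier-3 reference tiling.
#' @param ... passed to [place_scaffolds()].
#' @return list with `curation` and `placement` results.
#' @export
run_world_pipeline <- function(world, use_markers = TRUE,
                               use_tiling = TRUE, ...) {
  cur <- curate_scaffolds(world$scaffolds, world$reference$exons,
                          world$reference$exon_meta, world$synteny)
  pl <- place_scaffolds(cur$scaffolds, world$reference$exons,
                        world$reference$exon_meta, world$synteny,
                        markers = if (use_markers) world$markers,
                        reference = if (use_tiling) world$reference$genome,
                        ...)
  list(curation = cur, placement = pl)
}
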