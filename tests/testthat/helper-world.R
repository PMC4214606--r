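## Simulated worlds shared across test files, built once per test run.

.world_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.world_cache[[key]])) .world_cache[[key]] <- force(expr)
  .world_cache[[key]]
}

## compact world for unit tests: 2 x 300 kb, 20 genes, 8 fragments,
## 2 chimeras
small_world <- function() memo("small", simulate_world(
  sim_config(seed = 7, n_chromosomes = 2L, chrom_length = 3e5,
             n_genes = 20L, n_scaffold_fragments = 8L, n_chimeras = 2L,
             n_reads = 500L)))

small_curation <- function() {
  w <- small_world()
  memo("small_cur", curate_scaffolds(w$scaffolds, w$reference$exons,
                                     w$reference$exon_meta, w$synteny))
}

## the standard study-scale world: 3 x 2 Mb, 150 genes, 40 fragments,
## 5 chimeras, 1% divergence, seed 42
study_world <- function() memo("study", simulate_world(sim_config(seed = 42)))

study_pipeline <- function(use_markers = TRUE) {
  key <- paste0("study_pipe_", use_markers)
  memo(key, run_world_pipeline(study_world(), use_markers = use_markers))
}

## evidence data.frame builder for contiguity tests
make_evidence <- function(gene_id, exon_index, target_id, t_start, t_end,
                          strand) {
  data.frame(gene_id = gene_id, exon_index = exon_index,
             exon_id = paste0(gene_id, ".e", exon_index),
             ref_chrom = "ref1", ref_start = 1L, ref_end = 100L,
             ref_strand = "+", ref_pos = 50L, mapped = TRUE,
             target_id = target_id,
             t_lo = pmin(t_start, t_end), t_hi = pmax(t_start, t_end),
             t_start = t_start, t_end = t_end, strand = strand,
             identity = 100, aln_len = abs(t_end - t_start) + 1L,
             score = 100, stringsAsFactors = FALSE)
}

## internal constructor used to assemble decision tables in tests
placement_row <- function(...) scaftier:::placement_row(...)
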