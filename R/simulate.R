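#' Configuration for the synthetic-world simulator
#'
#' Defaults describe the standard test world: a 3-chromosome, 2-Mb-each
#' reference carrying 150 protein-coding genes; a target genome derived
#' from it by 1 percent per-site substitution and a block shuffle
#' (recorded as synteny truth); 40 scaffold fragments of which 5 pairs are
#' fused into cross-chromosome chimeras joined by a 100-N gap; an ordered
#' marker map at 50 markers/Mb; and 76-bp reads with 10 percent genomic
#' contamination.
#'
#' @param seed integer seed; mandatory (all randomness flows from it).
#' @param n_chromosomes,chrom_length reference shape.
#' @param n_genes,exons_per_gene,exon_length,intron_length gene shape
#'   (ranges are inclusive `c(min, max)`).
#' @param substitution_rate per-site substitution probability between
#'   reference and target (substitutions creating premature stops, or
#'   destroying a start/stop codon, are reverted -- purifying selection).
#' @param n_scaffold_fragments,n_chimeras,n_inversions fragmentation and
#'   planted misassemblies.
#' @param blocks_per_chromosome synteny blocks cut from each reference
#'   chromosome before shuffling.
#' @param marker_density,marker_length ordered-marker map (per Mb; bp).
#' @param read_length,n_reads,contamination_fraction read simulation.
#' @param chimera_gap N-gap length at planted junctions.
#' @return validated `sim_config` list.
#' @export
sim_config <- function(seed, n_chromosomes = 3L, chrom_length = 2e6,
                       n_genes = 150L, exons_per_gene = c(3L, 8L),
                       exon_length = c(90L, 240L),
                       intron_length = c(200L, 2000L),
                       substitution_rate = 0.01,
                       n_scaffold_fragments = 40L, n_chimeras = 5L,
                       n_inversions = 0L, blocks_per_chromosome = 2L,
                       marker_density = 50, marker_length = 120L,
                       read_length = 76L, n_reads = 2000L,
                       contamination_fraction = 0.1,
                       chimera_gap = 100L) {
  if (missing(seed) || is.null(seed)) stop("sim_config: seed is mandatory")
  if (substitution_rate < 0 || substitution_rate >= 1 ||
      contamination_fraction < 0 || contamination_fraction >= 1)
    stop("rates must lie in [0, 1)")
  if (any(c(n_chromosomes, chrom_length, n_genes, n_scaffold_fragments) <= 0))
    stop("counts must be positive")
  if (2L * n_chimeras > n_scaffold_fragments)
    stop("config infeasible: chimeras need 2 fragments each")
  cfg <- as.list(environment())
  max_span <- exons_per_gene[2L] * exon_length[2L] +
    (exons_per_gene[2L] - 1L) * intron_length[2L]
  slot <- chrom_length / ceiling(n_genes / n_chromosomes)
  if (slot < 1.5 * max_span)
    stop("config infeasible: more genes than fit on the chromosomes")
  structure(cfg, class = "sim_config")
}

COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

STOP_CODONS <- c("TAA", "TAG", "TGA")
SENSE_CODONS <- setdiff(
  as.vector(outer(outer(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                        paste0), c("T", "C", "A", "G"), paste0)),
  STOP_CODONS)

## genomic positions of a gene's transcript, 5'->3'
## exon_ranges: matrix (start,end) rows in transcript order
transcript_gpos <- function(exon_ranges, strand) {
  if (strand == "+")
    unlist(lapply(seq_len(nrow(exon_ranges)), function(i)
      exon_ranges[i, 1L]:exon_ranges[i, 2L]))
  else
    unlist(lapply(seq_len(nrow(exon_ranges)), function(i)
      exon_ranges[i, 2L]:exon_ranges[i, 1L]))
}

#' Simulate a complete test world with known truth
#'
#' Builds a reference species (chromosomes, genes, exon metadata, ortholog
#' proteome), a diverged block-shuffled target genome fragmented into
#' scaffolds with planted chimeras (and optionally inversions), an ordered
#' marker map and a synteny-block table -- everything the curation and
#' placement pipeline consumes, plus truth tables for every emitted
#' entity.  Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return a `sim_world` list with elements `config`, `reference`
#'   (`genome`, `exons`, `exon_meta`, `proteome`, `pairing`), `scaffolds`,
#'   `markers`, `synteny`, `target` (true chromosome sequences),
#'   `transcripts` (target CDS per gene) and `truth` (`scaffold_map`,
#'   `junctions`, `gene_scaffold`, `models`, `inversions`).
#' @export
simulate_world <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nc <- config$n_chromosomes
  L <- as.integer(config$chrom_length)
  bases <- c("A", "C", "G", "T")

  ref <- lapply(seq_len(nc), function(i) sample(bases, L, replace = TRUE))
  names(ref) <- paste0("ref", seq_len(nc))

  ## ---- genes on the reference --------------------------------------
  npc <- diff(round(seq(0, config$n_genes, length.out = nc + 1L)))
  genes <- list()
  gi <- 0L
  for (ci in seq_len(nc)) {
    slot <- L / npc[ci]
    for (j in seq_len(npc[ci])) {
      gi <- gi + 1L
      n_ex <- sample(config$exons_per_gene[1L]:config$exons_per_gene[2L], 1L)
      ex_lens <- sample(config$exon_length[1L]:config$exon_length[2L],
                        n_ex, replace = TRUE)
      total <- sum(ex_lens)
      ex_lens[n_ex] <- ex_lens[n_ex] - total %% 3L
      n_codons <- sum(ex_lens) %/% 3L
      cds <- paste0("ATG",
                    paste(sample(SENSE_CODONS, n_codons - 2L, replace = TRUE),
                          collapse = ""),
                    sample(STOP_CODONS, 1L))
      chunk_end <- cumsum(ex_lens)
      chunks <- substring(cds, c(1L, chunk_end[-n_ex] + 1L), chunk_end)
      introns <- if (n_ex > 1L)
        sample(config$intron_length[1L]:config$intron_length[2L], n_ex - 1L,
               replace = TRUE) else integer(0)
      strand <- sample(c("+", "-"), 1L)
      span <- sum(ex_lens) + sum(introns)
      center <- (j - 0.5) * slot + stats::runif(1L, -0.1, 0.1) * slot
      start <- max(1L, min(L - span, as.integer(round(center - span / 2))))
      ## genomic layout left-to-right; exon_ranges kept in transcript order
      g_chunks <- if (strand == "+") chunks
                  else rev(vapply(chunks, revcomp, character(1)))
      at <- start
      g_ranges <- matrix(0L, n_ex, 2L)
      for (k in seq_len(n_ex)) {
        len <- nchar(g_chunks[k])
        piece <- strsplit(g_chunks[k], "")[[1L]]
        ref[[ci]][at:(at + len - 1L)] <- piece
        g_ranges[k, ] <- c(at, at + len - 1L)
        if (k < n_ex) {
          ref[[ci]][(at + len):(at + len + introns[k] - 1L)] <-
            sample(bases, introns[k], replace = TRUE)
          at <- at + len + introns[k]
        } else at <- at + len
      }
      exon_ranges <- if (strand == "+") g_ranges
                     else g_ranges[n_ex:1L, , drop = FALSE]
      genes[[gi]] <- list(gene_id = sprintf("g%04d", gi),
                          ref_chrom = names(ref)[ci], ci = ci,
                          start = start, end = at - 1L, strand = strand,
                          n_ex = n_ex, cds = cds, chunks = chunks,
                          exon_ranges = exon_ranges)
    }
  }
  gene_tab <- data.frame(
    gene_id = vapply(genes, `[[`, "", "gene_id"),
    ref_chrom = vapply(genes, `[[`, "", "ref_chrom"),
    start = vapply(genes, `[[`, 0L, "start"),
    end = vapply(genes, `[[`, 0L, "end"),
    strand = vapply(genes, `[[`, "", "strand"),
    stringsAsFactors = FALSE)

  ## reference-side outputs
  exon_meta <- do.call(rbind, lapply(genes, function(g)
    data.frame(exon_id = sprintf("%s.e%d", g$gene_id, seq_len(g$n_ex)),
               gene_id = g$gene_id, exon_index = seq_len(g$n_ex),
               ref_chrom = g$ref_chrom,
               ref_start = g$exon_ranges[, 1L],
               ref_end = g$exon_ranges[, 2L],
               ref_strand = g$strand, stringsAsFactors = FALSE)))
  exon_seqs <- unlist(lapply(genes, function(g)
    stats::setNames(g$chunks, sprintf("%s.e%d", g$gene_id, seq_len(g$n_ex)))))
  proteome <- vapply(genes, function(g) {
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(g$cds)))
    substr(aa, 1L, nchar(aa) - 1L)
  }, character(1))
  names(proteome) <- paste0(vapply(genes, `[[`, "", "gene_id"), "_ref")
  pairing <- data.frame(gene_id = vapply(genes, `[[`, "", "gene_id"),
                        protein_id = names(proteome),
                        stringsAsFactors = FALSE)

  ## ---- diverged copy (substitutions, purifying selection in CDS) ----
  div <- ref
  if (config$substitution_rate > 0) {
    for (ci in seq_len(nc)) {
      n_sub <- stats::rbinom(1L, L, config$substitution_rate)
      pos <- sample.int(L, n_sub)
      old <- div[[ci]][pos]
      div[[ci]][pos] <- vapply(old, function(b)
        sample(setdiff(bases, b), 1L), character(1))
    }
    for (g in genes) {
      gpos <- transcript_gpos(g$exon_ranges, g$strand)
      chars <- div[[g$ci]][gpos]
      if (g$strand == "-") chars <- COMP[chars]
      n_codons <- length(chars) %/% 3L
      codons <- vapply(seq_len(n_codons), function(k)
        paste(chars[(3L * k - 2L):(3L * k)], collapse = ""), character(1))
      bad <- which(codons %in% STOP_CODONS & seq_len(n_codons) < n_codons)
      if (codons[1L] != "ATG") bad <- c(1L, bad)
      if (!codons[n_codons] %in% STOP_CODONS) bad <- c(bad, n_codons)
      for (k in bad) {
        p <- gpos[(3L * k - 2L):(3L * k)]
        div[[g$ci]][p] <- ref[[g$ci]][p]
      }
    }
  }

  ## ---- synteny blocks: cut each reference chromosome, shuffle -------
  intergenic_mid <- function(ci, want) {
    gt <- gene_tab[gene_tab$ref_chrom == names(ref)[ci], , drop = FALSE]
    gt <- gt[order(gt$start), , drop = FALSE]
    gaps_lo <- c(1L, gt$end + 1L)
    gaps_hi <- c(gt$start - 1L, L)
    mids <- (gaps_lo + gaps_hi) %/% 2L
    ok <- gaps_hi - gaps_lo > 10L
    mids <- mids[ok]
    mids[which.min(abs(mids - want))]
  }
  bpc <- config$blocks_per_chromosome
  blocks <- list()
  for (ci in seq_len(nc)) {
    cuts <- vapply(seq_len(bpc - 1L), function(k)
      intergenic_mid(ci, as.integer(round(L * k / bpc))), numeric(1))
    bounds <- c(0L, as.integer(cuts), L)
    for (k in seq_len(bpc))
      blocks[[length(blocks) + 1L]] <- list(
        ref_chrom = names(ref)[ci], ci = ci,
        ref_start = bounds[k] + 1L, ref_end = bounds[k + 1L])
  }
  perm <- sample(length(blocks))
  tgt_names <- as.character(seq_len(nc))
  assign_chrom <- rep(seq_len(nc), each = bpc)
  target <- stats::setNames(vector("list", nc), tgt_names)
  block_map <- list()
  for (t in seq_len(nc)) {
    at <- 0L
    for (bo in seq_len(bpc)) {
      b <- blocks[[perm[(t - 1L) * bpc + bo]]]
      orient <- sample(c("+", "-"), 1L)
      piece <- div[[b$ci]][b$ref_start:b$ref_end]
      if (orient == "-") piece <- rev(COMP[piece])
      target[[t]] <- c(target[[t]], piece)
      blen <- b$ref_end - b$ref_start + 1L
      block_map[[length(block_map) + 1L]] <- data.frame(
        ref_chrom = b$ref_chrom, ref_start = b$ref_start,
        ref_end = b$ref_end, target_chrom = tgt_names[t],
        block_orientation = orient, block_order = bo,
        t_start = at + 1L, t_end = at + blen, stringsAsFactors = FALSE)
      at <- at + blen
    }
  }
  block_map <- do.call(rbind, block_map)
  synteny <- block_map[, c("ref_chrom", "ref_start", "ref_end",
                           "target_chrom", "block_orientation",
                           "block_order")]

  ## gene coordinates on the target
  gene_target <- lapply(genes, function(g) {
    mid <- (g$start + g$end) %/% 2L
    bi <- which(block_map$ref_chrom == g$ref_chrom &
                block_map$ref_start <= mid & block_map$ref_end >= mid)[1L]
    b <- block_map[bi, ]
    to_t <- function(r) {
      if (b$block_orientation == "+") b$t_start + (r - b$ref_start)
      else b$t_start + (b$ref_end - r)
    }
    er <- g$exon_ranges
    t_ex <- cbind(pmin(to_t(er[, 1L]), to_t(er[, 2L])),
                  pmax(to_t(er[, 1L]), to_t(er[, 2L])))
    strand_t <- if (b$block_orientation == "+") g$strand
                else if (g$strand == "+") "-" else "+"
    list(gene_id = g$gene_id, target_chrom = b$target_chrom,
         t_start = min(t_ex), t_end = max(t_ex),
         exon_t = t_ex, strand_t = strand_t)
  })
  gt_tab <- data.frame(
    gene_id = vapply(gene_target, `[[`, "", "gene_id"),
    target_chrom = vapply(gene_target, `[[`, "", "target_chrom"),
    t_start = vapply(gene_target, function(x) x$t_start, numeric(1)),
    t_end = vapply(gene_target, function(x) x$t_end, numeric(1)),
    stringsAsFactors = FALSE)

  ## ---- fragmentation (cuts snapped to target intergenic gaps) -------
  t_lens <- vapply(target, length, integer(1))
  n_frag <- config$n_scaffold_fragments
  per_t <- pmax(1L, diff(round(seq(0, n_frag,
                                   length.out = nc + 1L))))
  frag <- list()
  for (t in seq_len(nc)) {
    tl <- t_lens[t]
    gt <- gt_tab[gt_tab$target_chrom == tgt_names[t], , drop = FALSE]
    gt <- gt[order(gt$t_start), , drop = FALSE]
    gaps_lo <- c(1, gt$t_end + 1)
    gaps_hi <- c(gt$t_start - 1, tl)
    mids <- (gaps_lo + gaps_hi) %/% 2
    mids <- mids[gaps_hi - gaps_lo > 10]
    want <- round(tl * seq_len(per_t[t] - 1L) / per_t[t])
    ## also force a cut near every internal block boundary
    bb <- block_map$t_end[block_map$target_chrom == tgt_names[t]]
    bb <- bb[bb < tl]
    for (w in bb) want[which.min(abs(want - w))] <- w
    cuts <- sort(unique(vapply(want, function(w)
      mids[which.min(abs(mids - w))], numeric(1))))
    bounds <- c(0, cuts, tl)
    for (k in seq_len(length(bounds) - 1L))
      frag[[length(frag) + 1L]] <- data.frame(
        target_chrom = tgt_names[t], t_start = bounds[k] + 1L,
        t_end = bounds[k + 1L], stringsAsFactors = FALSE)
  }
  frag <- do.call(rbind, frag)
  frag$frag_id <- sprintf("f%03d", seq_len(nrow(frag)))

  ## ---- chimera pairing and scaffold emission ------------------------
  avail <- frag$frag_id
  chim_pairs <- list()
  for (i in seq_len(config$n_chimeras)) {
    f1 <- sample(avail, 1L)
    c1 <- frag$target_chrom[frag$frag_id == f1]
    other <- avail[frag$target_chrom[match(avail, frag$frag_id)] != c1]
    f2 <- sample(other, 1L)
    chim_pairs[[i]] <- c(f1, f2)
    avail <- setdiff(avail, c(f1, f2))
  }
  units <- c(as.list(avail), chim_pairs)
  units <- units[sample(length(units))]
  scaffolds <- character(0)
  smap <- list()
  junctions <- list()
  for (u in seq_along(units)) {
    sid <- sprintf("s%03d", u)
    parts <- units[[u]]
    at <- 0L
    pieces <- character(0)
    for (p in seq_along(parts)) {
      fr <- frag[frag$frag_id == parts[p], ]
      flip <- sample(c("+", "-"), 1L)
      piece <- target[[fr$target_chrom]][fr$t_start:fr$t_end]
      if (flip == "-") piece <- rev(COMP[piece])
      if (p > 1L) {
        junctions[[length(junctions) + 1L]] <- data.frame(
          scaffold_id = sid, gap_start = at + 1L,
          gap_end = at + config$chimera_gap, stringsAsFactors = FALSE)
        pieces <- c(pieces, strrep("N", config$chimera_gap))
        at <- at + config$chimera_gap
      }
      plen <- length(piece)
      smap[[length(smap) + 1L]] <- data.frame(
        scaffold_id = sid, part = p, frag_id = parts[p],
        scaf_start = at + 1L, scaf_end = at + plen,
        target_chrom = fr$target_chrom, t_start = fr$t_start,
        t_end = fr$t_end, orientation = flip, stringsAsFactors = FALSE)
      pieces <- c(pieces, paste(piece, collapse = ""))
      at <- at + plen
    }
    scaffolds[sid] <- paste(pieces, collapse = "")
  }
  smap <- do.call(rbind, smap)
  junctions <- if (length(junctions)) do.call(rbind, junctions)
    else data.frame(scaffold_id = character(), gap_start = integer(),
                    gap_end = integer(), stringsAsFactors = FALSE)

  ## ---- true gene models on scaffolds -------------------------------
  models <- list()
  gene_scaffold <- list()
  for (i in seq_along(genes)) {
    g <- genes[[i]]; gtg <- gene_target[[i]]
    row <- smap[smap$target_chrom == gtg$target_chrom &
                smap$t_start <= gtg$t_start & smap$t_end >= gtg$t_end, ]
    if (nrow(row) != 1L) next  # gene split by fragmentation (avoided by design)
    to_s <- function(x) {
      if (row$orientation == "+") row$scaf_start + (x - row$t_start)
      else row$scaf_start + (row$t_end - x)
    }
    s_ex <- cbind(pmin(to_s(gtg$exon_t[, 1L]), to_s(gtg$exon_t[, 2L])),
                  pmax(to_s(gtg$exon_t[, 1L]), to_s(gtg$exon_t[, 2L])))
    strand_s <- if (row$orientation == "+") gtg$strand_t
                else if (gtg$strand_t == "+") "-" else "+"
    o <- order(s_ex[, 1L])
    s_ex <- s_ex[o, , drop = FALSE]
    widths <- s_ex[, 2L] - s_ex[, 1L] + 1L
    tr_order <- if (strand_s == "+") seq_len(nrow(s_ex))
                else rev(seq_len(nrow(s_ex)))
    cum <- cumsum(c(0L, widths[tr_order]))[seq_len(nrow(s_ex))]
    phase <- (3L - cum %% 3L) %% 3L
    cds <- cbind(s_ex, 0L)
    cds[tr_order, 3L] <- phase
    models[[g$gene_id]] <- gene_model(
      transcript_id = paste0(g$gene_id, ".t1"), gene_id = g$gene_id,
      chrom = row$scaffold_id, strand = strand_s, exons = s_ex, cds = cds,
      gene_name = toupper(g$gene_id),
      gene_description = paste("synthetic gene", g$gene_id))
    gene_scaffold[[length(gene_scaffold) + 1L]] <- data.frame(
      gene_id = g$gene_id, scaffold_id = row$scaffold_id,
      target_chrom = gtg$target_chrom, stringsAsFactors = FALSE)
  }
  gene_scaffold <- do.call(rbind, gene_scaffold)

  ## ---- planted inversions (orientation violations, not breaks) ------
  inversions <- data.frame(scaffold_id = character(), start = integer(),
                           end = integer(), gene_id = character(),
                           stringsAsFactors = FALSE)
  if (config$n_inversions > 0L) {
    single <- names(table(smap$scaffold_id))[table(smap$scaffold_id) == 1L]
    cand <- gene_scaffold[gene_scaffold$scaffold_id %in% single, ]
    cand <- cand[vapply(cand$gene_id, function(g)
      nrow(models[[g]]$exons) >= 3L, logical(1)), , drop = FALSE]
    pick <- cand[sample(nrow(cand), min(config$n_inversions, nrow(cand))), ]
    for (j in seq_len(nrow(pick))) {
      m <- models[[pick$gene_id[j]]]
      lo <- m$exons[2L, "start"]; hi <- m$exons[3L, "end"]
      s <- scaffolds[[pick$scaffold_id[j]]]
      scaffolds[pick$scaffold_id[j]] <- paste0(
        substr(s, 1L, lo - 1L), revcomp(substr(s, lo, hi)),
        substr(s, hi + 1L, nchar(s)))
      inversions <- rbind(inversions, data.frame(
        scaffold_id = pick$scaffold_id[j], start = lo, end = hi,
        gene_id = pick$gene_id[j], stringsAsFactors = FALSE))
      models[[pick$gene_id[j]]] <- NULL
    }
  }

  ## ---- ordered marker map -------------------------------------------
  spacing <- 1e6 / config$marker_density
  ml <- config$marker_length
  markers <- list()
  for (t in seq_len(nc)) {
    tl <- t_lens[t]
    pos <- seq(spacing / 2, tl - ml, by = spacing)
    pos <- as.integer(round(pos + stats::runif(length(pos), -0.2, 0.2) *
                              spacing))
    pos <- pmax(1L, pmin(as.integer(tl - ml), pos))
    fr <- frag[frag$target_chrom == tgt_names[t], ]
    inside <- vapply(pos, function(p)
      any(fr$t_start <= p & fr$t_end >= p + ml - 1L), logical(1))
    pos <- sort(pos[inside])
    seqs <- vapply(pos, function(p)
      paste(target[[t]][p:(p + ml - 1L)], collapse = ""), character(1))
    markers[[t]] <- data.frame(
      marker_id = sprintf("m%s_%04d", tgt_names[t], seq_along(pos)),
      chrom = tgt_names[t], order_index = seq_along(pos),
      sequence = seqs, t_pos = pos, stringsAsFactors = FALSE)
  }
  markers <- do.call(rbind, markers)

  ## target CDS (transcript) sequences, for read simulation
  transcripts <- vapply(genes, function(g) {
    gpos <- transcript_gpos(g$exon_ranges, g$strand)
    chars <- div[[g$ci]][gpos]
    if (g$strand == "-") chars <- COMP[chars]
    paste(chars, collapse = "")
  }, character(1))
  names(transcripts) <- vapply(genes, `[[`, "", "gene_id")

  structure(list(
    config = config,
    reference = list(
      genome = vapply(ref, paste, character(1), collapse = ""),
      exons = exon_seqs, exon_meta = exon_meta,
      proteome = proteome, pairing = pairing, genes = gene_tab),
    target = vapply(target, paste, character(1), collapse = ""),
    scaffolds = scaffolds, markers = markers, synteny = synteny,
    transcripts = transcripts,
    truth = list(scaffold_map = smap, junctions = junctions,
                 gene_scaffold = gene_scaffold, models = models,
                 inversions = inversions, gene_target = gt_tab)
  ), class = "sim_world")
}

#' @export
print.sim_world <- function(x, ...) {
  cat("sim_world: ", length(x$reference$genome), " reference chromosomes, ",
      length(x$scaffolds), " scaffolds, ",
      nrow(x$truth$junctions), " planted junctions, ",
      length(x$truth$models), " true gene models (seed ",
      x$config$seed, ")\n", sep = "")
  invisible(x)
}

#' Simulate mRNA reads with genomic contamination
#'
#' Error-free reads are drawn uniformly from the target transcript set;
#' a `contamination_fraction` of reads is drawn from intergenic target
#' sequence instead and labeled in the truth table.  Strand is random.
#' Transcriptomic reads align to the transcript set over their full
#' length, so the returned `aln_lengths` vector (read length for
#' transcript reads, absent for genomic reads) can drive
#' [filter_reads()] directly.
#'
#' @param world a [simulate_world()] result.
#' @param n_reads,read_length,contamination_fraction override the world
#'   config.
#' @param paired emit mate pairs (`/1`, `/2`; outer distance 3x read
#'   length) instead of single-end reads.
#' @param seed RNG seed; defaults to `config$seed + 1`.
#' @return list with `reads` ([Biostrings::QualityScaledDNAStringSet];
#'   for paired mode `reads1`/`reads2` as well), `truth` (data.frame
#'   `read_id, origin, source_id`), and `aln_lengths` (named numeric).
#' @export
simulate_reads <- function(world, n_reads = NULL, read_length = NULL,
                           contamination_fraction = NULL, paired = FALSE,
                           seed = NULL) {
  cfg <- world$config
  n <- if (is.null(n_reads)) cfg$n_reads else n_reads
  rl <- if (is.null(read_length)) cfg$read_length else read_length
  frac <- if (is.null(contamination_fraction)) cfg$contamination_fraction
          else contamination_fraction
  set.seed(if (is.null(seed)) cfg$seed + 1L else seed)

  tx <- world$transcripts[nchar(world$transcripts) >= rl]
  ## intergenic target intervals
  inter <- list()
  for (t in names(world$target)) {
    tl <- nchar(world$target[[t]])
    gt <- world$truth$gene_target
    gt <- gt[gt$target_chrom == t, , drop = FALSE]
    gt <- gt[order(gt$t_start), , drop = FALSE]
    lo <- c(1, gt$t_end + 1); hi <- c(gt$t_start - 1, tl)
    ok <- hi - lo + 1 >= rl
    if (any(ok))
      inter[[t]] <- data.frame(chrom = t, lo = lo[ok], hi = hi[ok])
  }
  inter <- do.call(rbind, inter)

  span <- if (paired) 3L * rl else rl
  genomic <- stats::runif(n) < frac
  ids <- sprintf("r%05d", seq_len(n))
  take <- function(src, at, len) substr(src, at, at + len - 1L)
  seq1 <- character(n); seq2 <- character(n); src_id <- character(n)
  for (i in seq_len(n)) {
    if (genomic[i]) {
      w <- sample.int(nrow(inter), 1L,
                      prob = pmax(1, inter$hi - inter$lo + 1 - span))
      lo <- inter$lo[w]; hi <- inter$hi[w]
      at <- lo + sample.int(max(1L, hi - lo + 1L - span), 1L) - 1L
      frg <- take(world$target[[inter$chrom[w]]], at, span)
      src_id[i] <- inter$chrom[w]
    } else {
      w <- sample.int(length(tx), 1L, prob = pmax(1, nchar(tx) - span))
      src <- tx[[w]]
      at <- sample.int(max(1L, nchar(src) - span + 1L), 1L)
      frg <- take(src, at, min(span, nchar(src) - at + 1L))
      src_id[i] <- names(tx)[w]
    }
    if (nchar(frg) < span) frg <- strrep(frg, ceiling(span / nchar(frg)))
    frg <- substr(frg, 1L, span)
    if (stats::runif(1) < 0.5) frg <- revcomp(frg)
    seq1[i] <- substr(frg, 1L, rl)
    seq2[i] <- revcomp(substr(frg, span - rl + 1L, span))
  }
  truth <- data.frame(read_id = ids,
                      origin = ifelse(genomic, "genomic", "transcript"),
                      source_id = src_id, stringsAsFactors = FALSE)
  qual <- strrep("I", rl)
  mk <- function(s, nm) Biostrings::QualityScaledDNAStringSet(
    stats::setNames(Biostrings::DNAStringSet(s), nm),
    Biostrings::PhredQuality(rep(qual, length(s))))
  if (paired) {
    r1 <- mk(seq1, paste0(ids, "/1")); r2 <- mk(seq2, paste0(ids, "/2"))
    aln <- stats::setNames(rep(rl, 2L * sum(!genomic)),
                           c(paste0(ids[!genomic], "/1"),
                             paste0(ids[!genomic], "/2")))
    list(reads1 = r1, reads2 = r2, reads = c(r1, r2), truth = truth,
         aln_lengths = aln)
  } else {
    r <- mk(seq1, ids)
    aln <- stats::setNames(rep(rl, sum(!genomic)), ids[!genomic])
    list(reads = r, truth = truth, aln_lengths = aln)
  }
}

#' Resolve post-break scaffold parts against simulator truth
#'
#' Maps each part produced by [apply_breaks()] back to the simulator's
#' fragment truth by maximal overlap through the provenance table, giving
#' every part its true chromosome, start and orientation.
#'
#' @param provenance data.frame from [apply_breaks()].
#' @param world a [simulate_world()] result.
#' @param scaffold_ids ids to resolve (parts and unbroken scaffolds).
#' @return data.frame `scaffold_id, target_chrom, t_start, orientation`.
#' @export
truth_for_parts <- function(provenance, world, scaffold_ids) {
  smap <- world$truth$scaffold_map
  out <- lapply(scaffold_ids, function(id) {
    pr <- provenance[provenance$part == id, , drop = FALSE]
    if (nrow(pr) == 1L) {
      parent <- pr$parent; lo <- pr$parent_start; hi <- pr$parent_end
    } else {
      parent <- id; lo <- 1L
      hi <- max(smap$scaf_end[smap$scaffold_id == id], 0L)
    }
    d <- smap[smap$scaffold_id == parent, , drop = FALSE]
    if (nrow(d) == 0L) return(NULL)
    ov <- pmax(0L, pmin(hi, d$scaf_end) - pmax(lo, d$scaf_start) + 1L)
    b <- d[which.max(ov), ]
    data.frame(scaffold_id = id, target_chrom = b$target_chrom,
               t_start = b$t_start, orientation = b$orientation,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write a simulated world to disk
#'
#' Emits exactly the file formats the pipeline consumes (FASTA, GTF, TSV)
#' plus truth tables under `truth/`.
#'
#' @param world a [simulate_world()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  write_fasta(world$scaffolds, file.path(dir, "scaffolds.fa"))
  write_fasta(world$reference$genome, file.path(dir, "reference_genome.fa"))
  write_fasta(world$reference$exons, file.path(dir, "reference_exons.fa"))
  write_fasta(world$reference$proteome,
              file.path(dir, "reference_proteome.fa"))
  tsv(world$reference$exon_meta, "exon_metadata.tsv")
  tsv(world$reference$pairing, "ortholog_pairing.tsv")
  tsv(world$markers[, c("marker_id", "chrom", "order_index", "sequence")],
      "markers.tsv")
  tsv(world$synteny, "synteny.tsv")
  write_gtf(world$truth$models, file.path(dir, "truth", "models.gtf"))
  tsv(world$truth$scaffold_map, "truth/scaffold_map.tsv")
  tsv(world$truth$junctions, "truth/junctions.tsv")
  tsv(world$truth$gene_scaffold, "truth/gene_scaffold.tsv")
  writeLines(paste0("seed\t", world$config$seed),
             file.path(dir, "truth", "seed.tsv"))
  invisible(dir)
}
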