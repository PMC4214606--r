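#' Detect contiguity-rule violations from exon evidence
#'
#' The contiguity rule requires that the exons of one gene lie on a single
#' scaffold, on one strand, with positions strictly monotone in transcript
#' order (increasing on `+`, decreasing on `-`).  For every gene with at
#' least two placed exons this reports:
#' \itemize{
#'   \item `split_gene` -- exons hit two or more scaffolds;
#'   \item `orientation_violation` -- mixed strands on one scaffold;
#'   \item `order_violation` -- positions not strictly monotone.
#' }
#' The result is independent of the input row order.
#'
#' @param evidence data.frame from [map_exons()].
#' @return data.frame with columns `gene_id, kind, scaffolds, detail`
#'   (scaffold ids comma-separated for split genes).
#' @export
detect_violations <- function(evidence) {
  ev <- evidence[evidence$mapped, , drop = FALSE]
  ev <- ev[order(ev$gene_id, ev$exon_index), , drop = FALSE]
  out <- list()
  for (g in unique(ev$gene_id)) {
    d <- ev[ev$gene_id == g, , drop = FALSE]
    if (nrow(d) < 2L) next
    scafs <- unique(d$target_id)
    if (length(scafs) > 1L) {
      out[[length(out) + 1L]] <- data.frame(
        gene_id = g, kind = "split_gene",
        scaffolds = paste(sort(scafs), collapse = ","),
        detail = sprintf("%d exons on %d scaffolds", nrow(d), length(scafs)),
        stringsAsFactors = FALSE)
      next
    }
    strands <- unique(d$strand)
    if (length(strands) > 1L) {
      out[[length(out) + 1L]] <- data.frame(
        gene_id = g, kind = "orientation_violation", scaffolds = scafs,
        detail = "exons on both strands of one scaffold",
        stringsAsFactors = FALSE)
    }
    pos <- d$t_start  # t_hi on minus strand, t_lo on plus (outfmt-6 style)
    ok <- if (length(strands) > 1L)
      all(diff(pos) > 0) || all(diff(pos) < 0)  # order judged independently
    else if (strands == "+") all(diff(pos) > 0) else all(diff(pos) < 0)
    if (!ok) {
      out[[length(out) + 1L]] <- data.frame(
        gene_id = g, kind = "order_violation", scaffolds = scafs,
        detail = paste("exon starts in transcript order:",
                       paste(pos, collapse = ",")),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(gene_id = character(), kind = character(),
                      scaffolds = character(), detail = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Assign each gene a chromosome vote from synteny
#'
#' Looks up every gene's reference position in the synteny-block table and
#' votes for the corresponding target chromosome.  Genes falling in no
#' block get `NA`.
#'
#' @param gene_metadata exon metadata data.frame ([read_exon_metadata()]).
#' @param synteny synteny-block data.frame ([read_synteny()]).
#' @return data.frame `gene_id, chrom, block_order, block_orientation,
#'   ref_chrom, ref_pos` (one row per gene; position is the median exon
#'   midpoint).
#' @export
gene_chromosome_votes <- function(gene_metadata, synteny) {
  mids <- (gene_metadata$ref_start + gene_metadata$ref_end) %/% 2L
  agg <- stats::aggregate(mids, by = list(gene_id = gene_metadata$gene_id,
                                          ref_chrom = gene_metadata$ref_chrom),
                          FUN = function(x) stats::median(x))
  names(agg)[3L] <- "ref_pos"
  bi <- mapply(function(ch, p) {
    hit <- which(synteny$ref_chrom == ch & synteny$ref_start <= p &
                 synteny$ref_end >= p)
    if (length(hit)) hit[1L] else NA_integer_
  }, agg$ref_chrom, agg$ref_pos)
  data.frame(gene_id = agg$gene_id,
             chrom = synteny$target_chrom[bi],
             block_order = synteny$block_order[bi],
             block_orientation = synteny$block_orientation[bi],
             ref_chrom = agg$ref_chrom, ref_pos = agg$ref_pos,
             stringsAsFactors = FALSE)
}

#' Detect chimeric scaffolds from positional gene clustering
#'
#' A scaffold is flagged as chimeric when the genes placed along it form
#' two or more maximal positional runs whose chromosome votes differ.
#' Runs shorter than `min_run_genes` (default 2) are treated as
#' single-gene noise: they never trigger a break on their own and are
#' reported separately for manual curation.
#'
#' @param evidence data.frame from [map_exons()].
#' @param votes data.frame from [gene_chromosome_votes()] (gene -> chrom).
#' @param min_run_genes minimum genes per run for the run to count as a
#'   cluster.
#' @return list with `clusters` (named list: per flagged scaffold a
#'   data.frame `chrom, start, end, n_genes` in scaffold order) and
#'   `noise` (data.frame of short-run genes left for curation).
#' @export
detect_chimeras <- function(evidence, votes, min_run_genes = 2L) {
  ev <- evidence[evidence$mapped, , drop = FALSE]
  ev$chrom <- votes$chrom[match(ev$gene_id, votes$gene_id)]
  ev <- ev[!is.na(ev$chrom), , drop = FALSE]
  ## per (scaffold, gene): span and vote
  key <- paste(ev$target_id, ev$gene_id, sep = "\r")
  gl <- data.frame(
    target_id = tapply(ev$target_id, key, `[`, 1L),
    gene_id = tapply(ev$gene_id, key, `[`, 1L),
    chrom = tapply(ev$chrom, key, `[`, 1L),
    start = as.integer(tapply(ev$t_lo, key, min)),
    end = as.integer(tapply(ev$t_hi, key, max)),
    pos = as.numeric(tapply((ev$t_lo + ev$t_hi) / 2, key, stats::median)),
    stringsAsFactors = FALSE)
  clusters <- list()
  noise <- list()
  for (s in sort(unique(gl$target_id))) {
    d <- gl[gl$target_id == s, , drop = FALSE]
    d <- d[order(d$pos), , drop = FALSE]
    r <- rle(d$chrom)
    ## a short run is single-gene noise only when it disagrees with the
    ## scaffold's majority vote; majority-vote genes are never noise
    maj <- majority(d$chrom)
    short <- rep(r$lengths < min_run_genes & r$values != maj, r$lengths)
    if (any(short))
      noise[[length(noise) + 1L]] <- data.frame(
        scaffold_id = s, gene_id = d$gene_id[short],
        chrom = d$chrom[short], stringsAsFactors = FALSE)
    keep <- d[!short, , drop = FALSE]
    if (nrow(keep) == 0L) next
    r2 <- rle(keep$chrom)
    if (length(r2$lengths) < 2L) next
    idx_end <- cumsum(r2$lengths)
    idx_start <- idx_end - r2$lengths + 1L
    clusters[[s]] <- data.frame(
      chrom = r2$values,
      start = as.integer(keep$start[idx_start]),
      end = as.integer(vapply(seq_along(idx_start), function(i)
        max(keep$end[idx_start[i]:idx_end[i]]), numeric(1))),
      n_genes = r2$lengths, stringsAsFactors = FALSE)
  }
  list(clusters = clusters,
       noise = if (length(noise)) do.call(rbind, noise)
               else data.frame(scaffold_id = character(),
                               gene_id = character(), chrom = character(),
                               stringsAsFactors = FALSE))
}

#' Propose breakpoints between conflicting evidence clusters
#'
#' One break per adjacent cluster pair.  The break coordinate is the
#' midpoint of the longest N-run strictly between the clusters, falling
#' back to the midpoint of the inter-cluster interval when no N-run
#' exists.  Coordinates count the bases kept in the left part: a break at
#' `c` splits a scaffold into `seq[1..c]` and `seq[(c+1)..len]`.
#'
#' @param clusters data.frame for one scaffold as produced by
#'   [detect_chimeras()] (`chrom, start, end`, ordered along the scaffold).
#' @param scaffold_seq the scaffold sequence (character).
#' @param scaffold_id scaffold name for the report.
#' @return data.frame `scaffold_id, coordinate, reason, evidence_left,
#'   evidence_right`.
#' @export
propose_breakpoints <- function(clusters, scaffold_seq,
                                scaffold_id = "scaffold") {
  if (nrow(clusters) < 2L)
    return(data.frame(scaffold_id = character(), coordinate = integer(),
                      reason = character(), evidence_left = character(),
                      evidence_right = character(), stringsAsFactors = FALSE))
  if (any(clusters$start[-1L] <= clusters$end[-nrow(clusters)]))
    stop("internal error: evidence clusters overlap")
  out <- lapply(seq_len(nrow(clusters) - 1L), function(i) {
    lo <- clusters$end[i]        # last evidence base of left cluster
    hi <- clusters$start[i + 1L] # first evidence base of right cluster
    gap <- substr(scaffold_seq, lo + 1L, hi - 1L)
    runs <- gregexpr("N+", gap)[[1L]]
    if (runs[1L] != -1L) {
      len <- attr(runs, "match.length")
      j <- which.max(len)
      a <- lo + as.integer(runs[j])          # first N (1-based on scaffold)
      coord <- a - 1L + len[j] %/% 2L
      reason <- sprintf("midpoint of longest N-run (%d bp)", len[j])
    } else {
      coord <- (lo + hi) %/% 2L
      reason <- "midpoint of inter-cluster interval (no N-run)"
    }
    data.frame(scaffold_id = scaffold_id, coordinate = coord,
               reason = reason,
               evidence_left = clusters$chrom[i],
               evidence_right = clusters$chrom[i + 1L],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Break scaffolds at proposed coordinates
#'
#' Each broken scaffold is replaced by parts named `<id>.1`, `<id>.2`, ...
#' left to right; unbroken scaffolds pass through unchanged.  The
#' provenance table maps every part back to its parent interval (1-based
#' inclusive), and concatenating the parts of a parent reproduces the
#' parent sequence exactly.
#'
#' @param scaffolds named character vector or [Biostrings::DNAStringSet].
#' @param breakpoints data.frame from [propose_breakpoints()] (possibly
#'   rows for several scaffolds).
#' @return list with `scaffolds` (named character vector) and `provenance`
#'   (data.frame `part, parent, parent_start, parent_end`).
#' @export
apply_breaks <- function(scaffolds, breakpoints) {
  seqs <- as_seq_vector(scaffolds)
  prov <- list()
  for (s in unique(breakpoints$scaffold_id)) {
    if (!s %in% names(seqs)) stop("breakpoint for unknown scaffold '", s, "'")
    len <- nchar(seqs[[s]])
    coords <- sort(unique(breakpoints$coordinate[breakpoints$scaffold_id == s]))
    if (any(coords <= 0L | coords >= len))
      stop("break coordinate out of range for scaffold '", s, "'")
    bounds <- c(0L, coords, len)
    starts <- bounds[-length(bounds)] + 1L
    ends <- bounds[-1L]
    parts <- substring(seqs[[s]], starts, ends)
    part_ids <- paste0(s, ".", seq_along(parts))
    names(parts) <- part_ids
    prov[[s]] <- data.frame(part = part_ids, parent = s,
                            parent_start = starts, parent_end = ends,
                            stringsAsFactors = FALSE)
    pos <- match(s, names(seqs))
    seqs <- append(seqs[-pos], parts, after = pos - 1L)
  }
  list(scaffolds = seqs,
       provenance = if (length(prov)) do.call(rbind, prov)
                    else data.frame(part = character(), parent = character(),
                                    parent_start = integer(),
                                    parent_end = integer(),
                                    stringsAsFactors = FALSE))
}
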