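#' Read an ordered marker map (radiation-hybrid style)
#'
#' @param path TSV with columns `marker_id, chrom, order_index` and
#'   optionally `sequence` (may be omitted when a precomputed hit table is
#'   used instead).
#' @return validated data.frame.
#' @export
read_markers <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("marker_id", "chrom", "order_index")
  if (!all(need %in% names(m)))
    stop("marker table '", path, "': need columns ",
         paste(need, collapse = ", "))
  m$chrom <- as.character(m$chrom)
  if (any(m$order_index < 1L)) stop("marker table: order_index must be >= 1")
  if (anyDuplicated(m[, c("chrom", "order_index")]))
    stop("marker table: duplicate (chrom, order_index)")
  m
}

#' Read a synteny-block table (FISH-map style)
#'
#' @param path TSV with columns `ref_chrom, ref_start, ref_end,
#'   target_chrom, block_orientation, block_order`.
#' @return validated data.frame.
#' @export
read_synteny <- function(path) {
  s <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("ref_chrom", "ref_start", "ref_end", "target_chrom",
            "block_orientation", "block_order")
  if (!all(need %in% names(s)))
    stop("synteny table '", path, "': need columns ",
         paste(need, collapse = ", "))
  s$ref_chrom <- as.character(s$ref_chrom)
  s$target_chrom <- as.character(s$target_chrom)
  if (any(s$ref_start > s$ref_end))
    stop("synteny table: ref_start > ref_end")
  if (anyDuplicated(s[, c("target_chrom", "block_order")]))
    stop("synteny table: duplicate block_order on one target chromosome")
  s
}

placement_row <- function(scaffold_id, chrom = NA_character_, tier = 0L,
                          orientation = NA_character_,
                          marker_key = NA_real_, block_order = NA_real_,
                          within_key = NA_real_, conflicts = "") {
  if (length(scaffold_id) == 0L)
    return(data.frame(scaffold_id = character(), chrom = character(),
                      tier = integer(), orientation = character(),
                      marker_key = numeric(), block_order = numeric(),
                      within_key = numeric(), conflicts = character(),
                      placed = logical(), stringsAsFactors = FALSE))
  data.frame(scaffold_id = scaffold_id, chrom = chrom, tier = tier,
             orientation = orientation, marker_key = marker_key,
             block_order = block_order, within_key = within_key,
             conflicts = conflicts, placed = !is.na(chrom),
             stringsAsFactors = FALSE)
}

majority <- function(x) {
  t <- sort(table(x), decreasing = TRUE)
  names(t)[1L]
}

#' Tier-1 placement from ordered markers
#'
#' Scaffolds containing mapped markers are assigned the markers'
#' chromosome; the order key is the median marker `order_index` and the
#' orientation is the sign of the correlation between marker order and
#' marker position on the scaffold.  Scaffolds whose markers disagree on
#' the chromosome are recorded as conflicts and left unplaced for
#' curation.
#'
#' @param markers marker data.frame ([read_markers()]); `sequence` column
#'   required unless `hit_table` is supplied.
#' @param index [build_index()] over the scaffold set.
#' @param hit_table precomputed hits ([read_aln_table()]) keyed by
#'   `marker_id`, used instead of the internal mapper when given.
#' @param min_identity,min_cov internal-mapper filters.
#' @return placement decision data.frame (`tier` 1, or 0 with a conflict).
#' @export
place_by_markers <- function(markers, index = NULL, hit_table = NULL,
                             min_identity = 95, min_cov = 0.9) {
  if (is.null(hit_table)) {
    if (is.null(index) || is.null(markers$sequence))
      stop("need an index and marker sequences, or a hit table")
    hits <- map_sequences(stats::setNames(markers$sequence,
                                          markers$marker_id),
                          index, min_identity = min_identity,
                          min_cov = min_cov)
  } else hits <- hit_table[hit_table$query_id %in% markers$marker_id, ,
                           drop = FALSE]
  best <- best_hits(hits)
  if (nrow(best) == 0L) return(placement_row(character(0)))
  best$chrom <- markers$chrom[match(best$query_id, markers$marker_id)]
  best$order_index <- markers$order_index[match(best$query_id,
                                                markers$marker_id)]
  best$tmid <- (best$t_lo + best$t_hi) / 2
  out <- lapply(sort(unique(best$target_id)), function(s) {
    d <- best[best$target_id == s, , drop = FALSE]
    chroms <- unique(d$chrom)
    if (length(chroms) > 1L)
      return(placement_row(s, conflicts = paste0(
        "tier1: markers disagree on chromosome (",
        paste(sort(chroms), collapse = ","), ")")))
    conf <- character(0)
    ori <- "+"
    if (nrow(d) >= 2L) {
      r <- suppressWarnings(stats::cor(d$order_index, d$tmid))
      if (is.na(r) || r == 0) conf <- c(conf, "tier1: orientation ambiguous")
      else ori <- if (r > 0) "+" else "-"
    } else conf <- c(conf, "tier1: single marker, orientation defaulted")
    placement_row(s, chrom = chroms, tier = 1L, orientation = ori,
                  marker_key = stats::median(d$order_index),
                  conflicts = paste(conf, collapse = "; "))
  })
  do.call(rbind, out)
}

#' Tier-2 placement from synteny blocks and ortholog positions
#'
#' Each gene's reference position locates it in a synteny block, which
#' votes for a target chromosome and block.  A scaffold is placed on the
#' majority chromosome; its within-block key is the median reference
#' position of its genes (reflected for minus-orientation blocks), and its
#' orientation is the block orientation times the majority
#' (exon-hit strand x reference gene strand) over its genes.
#'
#' @param scaffold_ids scaffolds still unplaced after tier 1.
#' @param evidence exon evidence ([map_exons()]).
#' @param synteny synteny blocks ([read_synteny()]).
#' @return placement decision data.frame (`tier` 2).
#' @export
place_by_synteny <- function(scaffold_ids, evidence, synteny) {
  votes <- gene_chromosome_votes(evidence, synteny)
  ev <- evidence[evidence$mapped & evidence$target_id %in% scaffold_ids, ,
                 drop = FALSE]
  if (nrow(ev) == 0L) return(placement_row(character(0)))
  vt <- votes[, c("gene_id", "chrom", "block_order", "block_orientation",
                  "ref_pos")]
  names(vt)[5L] <- "vote_pos"
  ev <- merge(ev, vt, by = "gene_id")
  ev <- ev[!is.na(ev$chrom), , drop = FALSE]
  out <- lapply(sort(unique(ev$target_id)), function(s) {
    d <- ev[ev$target_id == s, , drop = FALSE]
    conf <- character(0)
    chrom <- majority(d$chrom)
    if (length(unique(d$chrom)) > 1L)
      conf <- c(conf, "tier2: genes vote for multiple chromosomes")
    d <- d[d$chrom == chrom, , drop = FALSE]
    block <- as.numeric(majority(d$block_order))
    if (length(unique(d$block_order)) > 1L)
      conf <- c(conf, "tier2: genes fall in multiple blocks; majority used")
    db <- d[d$block_order == block, , drop = FALSE]
    bo <- db$block_orientation[1L]
    gene_pos <- tapply(db$vote_pos, db$gene_id, `[`, 1L)
    med <- stats::median(gene_pos)
    ## orientation per gene: majority exon strand on scaffold times the
    ## gene's strand on the reference
    gsign <- vapply(unique(db$gene_id), function(g) {
      dg <- db[db$gene_id == g, , drop = FALSE]
      hs <- if (majority(dg$strand) == "+") 1 else -1
      rs <- if (dg$ref_strand[1L] == "+") 1 else -1
      hs * rs
    }, numeric(1))
    m <- sum(gsign)
    if (m == 0) conf <- c(conf, "tier2: orientation tie, defaulted +")
    msign <- if (m >= 0) 1 else -1
    bsign <- if (bo == "+") 1 else -1
    placement_row(s, chrom = chrom, tier = 2L,
                  orientation = if (bsign * msign > 0) "+" else "-",
                  block_order = block,
                  within_key = if (bo == "+") med else -med,
                  conflicts = paste(conf, collapse = "; "))
  })
  do.call(rbind, out)
}

#' Tier-3 placement by reference-chromosome segment tiling
#'
#' Reference chromosomes are cut into consecutive fixed-size segments
#' (terminal segments may be shorter) and each segment's best hit on a
#' still-unplaced scaffold casts a vote.  A scaffold is placed at the
#' synteny-block position of its median voting segment, ordered by
#' reference position; orientation is block orientation times the majority
#' hit strand.
#'
#' @param scaffolds named character vector of still-unplaced scaffolds.
#' @param reference named character vector of reference chromosomes.
#' @param synteny synteny blocks ([read_synteny()]).
#' @param tiling_segment_bp segment size (default 10000).
#' @param min_identity,min_cov mapper filters (coverage is per segment and
#'   deliberately loose so segments spanning scaffold ends still vote).
#' @param k k-mer size for the throwaway index over `scaffolds`.
#' @return placement decision data.frame (`tier` 3).
#' @export
place_by_tiling <- function(scaffolds, reference, synteny,
                            tiling_segment_bp = 10000L, min_identity = 90,
                            min_cov = 0.25, k = 15L) {
  seqs <- as_seq_vector(scaffolds)
  refs <- as_seq_vector(reference)
  if (length(seqs) == 0L) return(placement_row(character(0)))
  idx <- build_index(seqs, k = k)
  segs <- list()
  for (ch in names(refs)) {
    starts <- seq(1L, nchar(refs[[ch]]), by = tiling_segment_bp)
    ends <- pmin(starts + tiling_segment_bp - 1L, nchar(refs[[ch]]))
    x <- substring(refs[[ch]], starts, ends)
    names(x) <- sprintf("%s|%d", ch, seq_along(starts))
    segs[[ch]] <- x
  }
  segs <- unlist(unname(segs))
  hits <- map_sequences(segs, idx, min_identity = min_identity,
                        min_cov = min_cov)
  best <- best_hits(hits)
  if (nrow(best) == 0L) return(placement_row(character(0)))
  parts <- strsplit(best$query_id, "|", fixed = TRUE)
  best$ref_chrom <- vapply(parts, `[`, "", 1L)
  best$segment_index <- as.integer(vapply(parts, `[`, "", 2L))
  out <- lapply(sort(unique(best$target_id)), function(s) {
    d <- best[best$target_id == s, , drop = FALSE]
    conf <- character(0)
    rc <- majority(d$ref_chrom)
    if (length(unique(d$ref_chrom)) > 1L)
      conf <- c(conf, "tier3: segments vote for multiple reference chromosomes")
    d <- d[d$ref_chrom == rc, , drop = FALSE]
    med_idx <- stats::median(d$segment_index)
    ref_pos <- (med_idx - 0.5) * tiling_segment_bp
    bi <- which(synteny$ref_chrom == rc & synteny$ref_start <= ref_pos &
                synteny$ref_end >= ref_pos)
    if (!length(bi))
      return(placement_row(s, conflicts =
        "tier3: median segment falls in no synteny block"))
    bo <- synteny$block_orientation[bi[1L]]
    m <- sum(ifelse(d$strand == "+", 1, -1))
    if (m == 0) conf <- c(conf, "tier3: orientation tie, defaulted +")
    msign <- if (m >= 0) 1 else -1
    bsign <- if (bo == "+") 1 else -1
    placement_row(s, chrom = synteny$target_chrom[bi[1L]], tier = 3L,
                  orientation = if (bsign * msign > 0) "+" else "-",
                  block_order = synteny$block_order[bi[1L]],
                  within_key = if (bo == "+") ref_pos else -ref_pos,
                  conflicts = paste(conf, collapse = "; "))
  })
  do.call(rbind, out)
}

#' Merge tiered placements into a chromosome table
#'
#' Decisions from the three tiers are combined (a scaffold keeps its
#' lowest-tier decision) and each chromosome is linearized:
#' marker-bearing scaffolds are ordered by marker key; scaffolds with only
#' block evidence are inserted between the marker-ordered scaffolds using
#' scaffolds that carry both kinds of evidence as anchors (so marker order
#' wins where the two sources disagree, and the disagreement is recorded
#' as a conflict).  An optional override table is applied last and wins.
#'
#' @param decisions data.frame or list of data.frames of placement
#'   decisions from the `place_by_*` functions.
#' @param override optional data.frame `scaffold_id, chrom, position,
#'   orientation` (curation file); `position` is the 1-based slot in the
#'   final per-chromosome order.
#' @param all_scaffolds optional character vector of every input scaffold
#'   id, used to report the unplaced remainder.
#' @return list with `table` (data.frame `chrom, position, scaffold_id,
#'   orientation, tier, conflicts`) and `unplaced` (character vector).
#' @export
merge_placements <- function(decisions, override = NULL,
                             all_scaffolds = NULL) {
  if (is.list(decisions) && !is.data.frame(decisions))
    decisions <- do.call(rbind, decisions)
  d <- decisions[order(decisions$scaffold_id, decisions$tier == 0L,
                       decisions$tier), , drop = FALSE]
  d <- d[!duplicated(d$scaffold_id), , drop = FALSE]  # tier monotonicity
  placed <- d[d$placed, , drop = FALSE]
  tabs <- lapply(sort(unique(placed$chrom)), function(ch) {
    x <- order_chromosome(placed[placed$chrom == ch, , drop = FALSE])
    x$chrom <- ch
    x
  })
  empty <- data.frame(scaffold_id = character(), orientation = character(),
                      tier = integer(), conflicts = character(),
                      chrom = character(), stringsAsFactors = FALSE)
  tab <- if (length(tabs)) do.call(rbind, tabs) else empty
  if (!is.null(override) && nrow(override)) {
    known <- union(d$scaffold_id, all_scaffolds)
    bad <- setdiff(override$scaffold_id, known)
    if (length(bad))
      stop("override references unknown scaffold '", bad[1L], "'")
    bychr <- split(tab, tab$chrom)
    for (i in seq_len(nrow(override))) {
      o <- override[i, , drop = FALSE]
      bychr <- lapply(bychr, function(x)
        x[x$scaffold_id != o$scaffold_id, , drop = FALSE])
      newrow <- data.frame(scaffold_id = o$scaffold_id,
                           orientation = o$orientation, tier = NA_integer_,
                           conflicts = "override", chrom = o$chrom,
                           stringsAsFactors = FALSE)
      cur <- bychr[[o$chrom]]
      if (is.null(cur)) cur <- empty
      at <- min(max(o$position, 1L), nrow(cur) + 1L)
      bychr[[o$chrom]] <- rbind(cur[seq_len(at - 1L), , drop = FALSE],
                                newrow,
                                if (at <= nrow(cur))
                                  cur[at:nrow(cur), , drop = FALSE])
    }
    tab <- do.call(rbind, bychr[order(names(bychr))])
  }
  if (nrow(tab)) {
    tab <- tab[order(tab$chrom), , drop = FALSE]
    tab$position <- unlist(lapply(split(seq_len(nrow(tab)), tab$chrom),
                                  seq_along), use.names = FALSE)
  } else tab$position <- integer(0)
  tab <- tab[, c("chrom", "position", "scaffold_id", "orientation",
                 "tier", "conflicts")]
  rownames(tab) <- NULL
  unplaced <- setdiff(union(all_scaffolds, d$scaffold_id),
                      tab$scaffold_id)
  list(table = tab, unplaced = sort(unplaced))
}

## linearize the scaffolds of one chromosome; see merge_placements
order_chromosome <- function(d) {
  d$wk <- ifelse(is.na(d$within_key), 0, d$within_key)
  has_m <- !is.na(d$marker_key)
  has_b <- !is.na(d$block_order)
  if (!any(has_m)) {
    o <- order(d$block_order, d$wk, d$tier, d$scaffold_id)
    res <- d[o, , drop = FALSE]
  } else {
    A <- d[has_m, , drop = FALSE]
    A <- A[order(A$marker_key, A$scaffold_id), , drop = FALSE]
    A$key <- seq_len(nrow(A))
    B <- d[!has_m, , drop = FALSE]
    if (nrow(B)) {
      anchors <- A[!is.na(A$block_order), , drop = FALSE]
      B <- B[order(B$block_order, B$wk, B$tier, B$scaffold_id), ,
             drop = FALSE]
      if (nrow(anchors) == 0L) {
        B$conflicts <- paste0(B$conflicts,
          "; merge: no marker anchors on chromosome, appended after tier 1")
        B$key <- nrow(A) + seq_len(nrow(B))
      } else {
        B$key <- vapply(seq_len(nrow(B)), function(i) {
          less <- anchors$block_order < B$block_order[i] |
            (anchors$block_order == B$block_order[i] &
             anchors$wk < B$wk[i])
          base <- if (any(less)) max(anchors$key[less]) else 0
          base + i / (nrow(B) + 1)
        }, numeric(1))
      }
    }
    res <- rbind(A, B)
    res <- res[order(res$key), , drop = FALSE]
  }
  res[, c("scaffold_id", "orientation", "tier", "conflicts")]
}
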