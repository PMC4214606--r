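#' Default thresholds for gene-model quality control
#'
#' The acceptance rule expects a test protein and its ortholog to differ
#' by fewer than `max_len_diff` amino acids in length and to exceed
#' `min_similarity` percent similarity; alignment scoring uses
#' Needleman-Wunsch with affine gaps (BLOSUM62, open 10, extend 0.5, free
#' end gaps).  The `fast_evolving` gene class relaxes both cutoffs for
#' gene families known to diverge quickly (immune, reproductive).
#'
#' @param max_len_diff maximum tolerated protein length difference (aa,
#'   strict: a difference equal to this value is not accepted).
#' @param min_similarity minimum percent similarity (strict).
#' @param terminal_merge_max maximum genomic distance (bp) across which
#'   non-coding terminal exons are merged.
#' @param gap_open,gap_extend affine gap penalties.
#' @param fast_len_diff,fast_min_similarity cutoffs for the
#'   `fast_evolving` class.
#' @return list of thresholds.
#' @export
qc_thresholds <- function(max_len_diff = 5, min_similarity = 92,
                          terminal_merge_max = 1000L, gap_open = 10,
                          gap_extend = 0.5, fast_len_diff = 15,
                          fast_min_similarity = 80) {
  stopifnot(max_len_diff > 0, min_similarity > 0, min_similarity <= 100,
            terminal_merge_max > 0, gap_open > 0, gap_extend > 0)
  list(max_len_diff = max_len_diff, min_similarity = min_similarity,
       terminal_merge_max = terminal_merge_max, gap_open = gap_open,
       gap_extend = gap_extend, fast_len_diff = fast_len_diff,
       fast_min_similarity = fast_min_similarity)
}

#' Extract the coding sequence of a gene model from the genome
#'
#' CDS intervals are concatenated 5' to 3' (reverse-complemented and
#' read right-to-left on the minus strand) and leading bases are trimmed
#' according to the phase of the transcript's first CDS interval.
#'
#' @param model a [gene_model()].
#' @param genome named character vector or [Biostrings::DNAStringSet].
#' @return the CDS as a character string.
#' @export
extract_cds <- function(model, genome) {
  seqs <- as_seq_vector(genome)
  if (!model$chrom %in% names(seqs))
    stop("chromosome '", model$chrom, "' not in genome")
  chrom <- seqs[[model$chrom]]
  cds <- model$cds
  if (nrow(cds) == 0L) stop("gene model '", model$transcript_id,
                            "' has no CDS")
  if (any(cds[, "end"] > nchar(chrom)) || any(cds[, "start"] < 1L))
    stop("CDS interval out of bounds for '", model$transcript_id, "'")
  pieces <- substring(chrom, cds[, "start"], cds[, "end"])
  if (model$strand == "+") {
    out <- paste(pieces, collapse = "")
    phase <- cds[1L, "phase"]
  } else {
    out <- revcomp(paste(pieces, collapse = ""))
    phase <- cds[nrow(cds), "phase"]  # first interval in transcript order
  }
  substr(out, phase + 1L, nchar(out))
}

#' Translate a CDS with structural flags
#'
#' Standard genetic code.  The terminal stop is removed from the returned
#' protein.  Flags (never exceptions) record structural problems:
#' `internal_stop`, `no_start` (first residue is not M), and
#' `incomplete_codon` (length not a multiple of 3; trailing bases are
#' ignored).
#'
#' @param cds DNA string (length >= 3).
#' @return list with `protein` (character, internal stops as `*`) and
#'   `flags` (character vector).
#' @export
translate_cds <- function(cds) {
  if (nchar(cds) < 3L) stop("CDS shorter than one codon")
  flags <- character(0)
  n <- nchar(cds)
  if (n %% 3L != 0L) {
    flags <- c(flags, "incomplete_codon")
    cds <- substr(cds, 1L, n - n %% 3L)
  }
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                           if.fuzzy.codon = "X"))
  if (substr(aa, nchar(aa), nchar(aa)) == "*")
    aa <- substr(aa, 1L, nchar(aa) - 1L)
  if (grepl("*", aa, fixed = TRUE)) flags <- c(flags, "internal_stop")
  if (substr(aa, 1L, 1L) != "M") flags <- c(flags, "no_start")
  list(protein = aa, flags = flags)
}

#' Global protein alignment with identity/similarity/gap summary
#'
#' Needleman-Wunsch with affine gap penalties over BLOSUM62, with free end
#' gaps (the EMBOSS needle default).  Statistics are computed over the
#' full end-to-end alignment: identity is the fraction of identical
#' columns, similarity the fraction of columns with a positive
#' substitution score (identities included), and `gap_positions` the total
#' number of gap characters in both rows (end gaps included), so
#' `gap_positions >= abs(len_a - len_b)` always holds.
#'
#' @param a,b protein sequences (no `*` or other non-residue symbols).
#' @param thresholds [qc_thresholds()] list (gap penalties are read from
#'   it).
#' @return list with `identity`, `similarity`, `gap_positions`,
#'   `gap_percent`, `score`, and `alignment` (character vector of the two
#'   aligned rows).
#' @export
global_align <- function(a, b, thresholds = qc_thresholds()) {
  mat <- blosum62()
  ok <- setdiff(rownames(mat), "*")
  for (s in c(a, b))
    if (grepl(sprintf("[^%s]", paste(ok, collapse = "")), s))
      stop("non-amino-acid symbol in protein sequence")
  if (!nzchar(a) || !nzchar(b)) stop("empty protein sequence")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = mat, gapOpening = thresholds$gap_open,
    gapExtension = thresholds$gap_extend, type = "overlap")
  pat <- as.character(Biostrings::alignedPattern(pa))
  sub <- as.character(Biostrings::alignedSubject(pa))
  ## reconstruct the full end-to-end alignment: unaligned prefixes and
  ## suffixes become (free) end gaps, stacked pattern-first
  ps <- start(Biostrings::pattern(pa)); pe <- end(Biostrings::pattern(pa))
  ss <- start(Biostrings::subject(pa)); se <- end(Biostrings::subject(pa))
  a_pre <- substr(a, 1L, ps - 1L); a_suf <- substr(a, pe + 1L, nchar(a))
  b_pre <- substr(b, 1L, ss - 1L); b_suf <- substr(b, se + 1L, nchar(b))
  row_a <- paste0(a_pre, strrep("-", nchar(b_pre)), pat,
                  a_suf, strrep("-", nchar(b_suf)))
  row_b <- paste0(strrep("-", nchar(a_pre)), b_pre, sub,
                  strrep("-", nchar(a_suf)), b_suf)
  ca <- strsplit(row_a, "")[[1L]]
  cb <- strsplit(row_b, "")[[1L]]
  len <- length(ca)
  gap <- ca == "-" | cb == "-"
  ident <- sum(!gap & ca == cb)
  simil <- sum(mat[cbind(ca[!gap], cb[!gap])] > 0)
  list(identity = 100 * ident / len,
       similarity = 100 * simil / len,
       gap_positions = sum(ca == "-") + sum(cb == "-"),
       gap_percent = 100 * (sum(ca == "-") + sum(cb == "-")) / (2 * len),
       score = score(pa),
       alignment = c(row_a, row_b))
}

## BLOSUM62 loaded once per session
blosum_cache <- new.env(parent = emptyenv())
blosum62 <- function() {
  if (is.null(blosum_cache$mat)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    blosum_cache$mat <- e$BLOSUM62
  }
  blosum_cache$mat
}

#' Apply the ortholog acceptance rule to a protein comparison
#'
#' Accept if and only if the protein length difference is strictly below
#' `max_len_diff` and the similarity is strictly above `min_similarity`
#' (relaxed cutoffs for the `fast_evolving` class) and no structural flag
#' is present.  Everything else is flagged for manual review; nothing is
#' silently rejected.
#'
#' @param comparison list or one-row data.frame with `len_test`,
#'   `len_ref`, `similarity` and optionally `flags`.
#' @param gene_class `"default"` or `"fast_evolving"`.
#' @param thresholds [qc_thresholds()].
#' @return `"accept"` or `"flag_for_review"`.
#' @export
evaluate_model <- function(comparison, gene_class = "default",
                           thresholds = qc_thresholds()) {
  max_dl <- if (gene_class == "fast_evolving") thresholds$fast_len_diff
            else thresholds$max_len_diff
  min_sim <- if (gene_class == "fast_evolving")
               thresholds$fast_min_similarity
             else thresholds$min_similarity
  flags <- comparison$flags
  flagged <- length(flags) > 0 && any(nzchar(unlist(strsplit(
    paste(flags, collapse = ","), ","))))
  if (!flagged &&
      abs(comparison$len_test - comparison$len_ref) < max_dl &&
      comparison$similarity > min_sim) "accept" else "flag_for_review"
}

#' Compare annotated proteins with their ortholog proteins
#'
#' For every gene model: extract and translate the CDS, align the protein
#' to its paired ortholog, and apply the acceptance rule.  Proteins with
#' an internal stop are truncated at the first stop for alignment and are
#' always flagged for review.
#'
#' @param models named list of [gene_model()]s.
#' @param genome named character vector or [Biostrings::DNAStringSet].
#' @param proteome named character vector or [Biostrings::AAStringSet] of
#'   ortholog proteins.
#' @param pairing data.frame `gene_id, protein_id` linking models to
#'   ortholog proteins.
#' @param thresholds [qc_thresholds()].
#' @param gene_classes optional data.frame `gene_id, class`
#'   (`default`/`fast_evolving`).
#' @return data.frame, one row per model: `gene_id, transcript_id,
#'   len_test, len_ref, identity, similarity, gap_positions, gap_percent,
#'   flags, decision`.
#' @export
compare_proteins <- function(models, genome, proteome, pairing,
                             thresholds = qc_thresholds(),
                             gene_classes = NULL) {
  prot <- as_seq_vector(proteome)
  out <- lapply(models, function(m) {
    pid <- pairing$protein_id[match(m$gene_id, pairing$gene_id)]
    if (is.na(pid) || !pid %in% names(prot))
      stop("no ortholog protein paired with gene '", m$gene_id, "'")
    tr <- translate_cds(extract_cds(m, genome))
    test <- tr$protein
    flags <- tr$flags
    if ("internal_stop" %in% flags)
      test <- sub("\\*.*$", "", test)
    ref <- prot[[pid]]
    cls <- "default"
    if (!is.null(gene_classes)) {
      i <- match(m$gene_id, gene_classes$gene_id)
      if (!is.na(i)) cls <- gene_classes$class[i]
    }
    al <- global_align(test, ref, thresholds)
    cmp <- list(len_test = nchar(test), len_ref = nchar(ref),
                similarity = al$similarity, flags = flags)
    data.frame(gene_id = m$gene_id, transcript_id = m$transcript_id,
               len_test = nchar(test), len_ref = nchar(ref),
               identity = al$identity, similarity = al$similarity,
               gap_positions = al$gap_positions,
               gap_percent = al$gap_percent,
               flags = paste(flags, collapse = ","),
               decision = evaluate_model(cmp, cls, thresholds),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Merge non-coding terminal exons separated by a short gap
#'
#' When both the 3'-most (terminal) exon and the 3' end of the penultimate
#' exon are non-coding and the genomic distance between the two exons does
#' not exceed `terminal_merge_max`, the two exons and the intervening
#' sequence are merged into a single new terminal exon.  CDS intervals are
#' never modified; models that do not satisfy the conditions are returned
#' unchanged.
#'
#' @param model a [gene_model()] with at least two exons.
#' @param thresholds [qc_thresholds()].
#' @return possibly-modified [gene_model()].
#' @export
merge_terminal_exons <- function(model, thresholds = qc_thresholds()) {
  ex <- model$exons
  if (nrow(ex) < 2L) return(model)
  cds <- model$cds
  in_cds <- function(pos) nrow(cds) > 0L &&
    any(cds[, "start"] <= pos & cds[, "end"] >= pos)
  overlaps_cds <- function(lo, hi) nrow(cds) > 0L &&
    any(cds[, "start"] <= hi & cds[, "end"] >= lo)
  if (model$strand == "+") {
    term <- nrow(ex); pen <- term - 1L
    pen_3p <- ex[pen, "end"]
    gap <- ex[term, "start"] - ex[pen, "end"] - 1L
  } else {
    term <- 1L; pen <- 2L
    pen_3p <- ex[pen, "start"]
    gap <- ex[pen, "start"] - ex[term, "end"] - 1L
  }
  if (in_cds(pen_3p)) return(model)
  if (overlaps_cds(ex[term, "start"], ex[term, "end"])) return(model)
  if (gap > thresholds$terminal_merge_max) return(model)
  lo <- min(ex[pen, "start"], ex[term, "start"])
  hi <- max(ex[pen, "end"], ex[term, "end"])
  keep <- ex[-c(pen, term), , drop = FALSE]
  newex <- rbind(keep, c(lo, hi))
  gene_model(model$transcript_id, model$gene_id, model$chrom, model$strand,
             newex, if (nrow(cds)) cds else NULL, model$gene_name,
             model$gene_description)
}

#' Extend a terminal exon through the projected 3' UTR
#'
#' Projects the ortholog's 3' UTR length onto the model by extending the
#' terminal exon downstream, provided the downstream genomic sequence is
#' gap-free (no `N`) and stays inside the chromosome.  Projection is by
#' length, not alignment.
#'
#' @param model a [gene_model()].
#' @param genome named character vector or [Biostrings::DNAStringSet].
#' @param ref_utr_len ortholog 3' UTR length in bp.
#' @return possibly-extended [gene_model()].
#' @export
extend_terminal_utr <- function(model, genome, ref_utr_len) {
  seqs <- as_seq_vector(genome)
  chrom <- seqs[[model$chrom]]
  ex <- model$exons
  if (model$strand == "+") {
    term <- nrow(ex)
    cds_end <- if (nrow(model$cds)) max(model$cds[, "end"]) else ex[term, "end"]
    cur <- ex[term, "end"] - cds_end
    add <- ref_utr_len - cur
    if (add <= 0L) return(model)
    new_end <- min(ex[term, "end"] + add, nchar(chrom))
    if (grepl("N", substr(chrom, ex[term, "end"] + 1L, new_end))) return(model)
    ex[term, "end"] <- new_end
  } else {
    term <- 1L
    cds_start <- if (nrow(model$cds)) min(model$cds[, "start"])
                 else ex[term, "start"]
    cur <- cds_start - ex[term, "start"]
    add <- ref_utr_len - cur
    if (add <= 0L) return(model)
    new_start <- max(ex[term, "start"] - add, 1L)
    if (grepl("N", substr(chrom, new_start, ex[term, "start"] - 1L)))
      return(model)
    ex[term, "start"] <- new_start
  }
  gene_model(model$transcript_id, model$gene_id, model$chrom, model$strand,
             ex, if (nrow(model$cds)) model$cds else NULL, model$gene_name,
             model$gene_description)
}

#' Validate gene-model structure and remove duplicate transcripts
#'
#' Issues are reported for CDS intervals not contained in any exon,
#' overlapping exons within a transcript, and invalid strands.  Duplicate
#' transcripts (identical chromosome, strand, exon set and CDS set) are
#' removed, keeping the lexicographically smallest transcript id.
#' Validation is idempotent: running it on its own clean output yields no
#' issues.
#'
#' @param models named list of [gene_model()]s, or a list of raw lists
#'   with the same fields (so broken models can be checked before
#'   construction).
#' @return list with `models` (clean, named list) and `issues`
#'   (data.frame `transcript_id, issue, detail`).
#' @export
validate_gtf <- function(models) {
  issues <- list()
  note <- function(tid, issue, detail = "")
    issues[[length(issues) + 1L]] <<- data.frame(
      transcript_id = tid, issue = issue, detail = detail,
      stringsAsFactors = FALSE)
  ok <- logical(length(models))
  for (i in seq_along(models)) {
    m <- models[[i]]
    m$exons <- interval_matrix(m$exons, c("start", "end"))
    m$cds <- interval_matrix(m$cds, c("start", "end", "phase"))
    models[[i]] <- m
    good <- TRUE
    if (!m$strand %in% c("+", "-")) {
      note(m$transcript_id, "invalid_strand", m$strand)
      good <- FALSE
    }
    ex <- m$exons[order(m$exons[, "start"]), , drop = FALSE]
    if (nrow(ex) > 1L && any(ex[-1L, "start"] <= ex[-nrow(ex), "end"])) {
      note(m$transcript_id, "overlapping_exons")
      good <- FALSE
    }
    cds <- m$cds
    for (j in seq_len(nrow(cds))) {
      hit <- which(ex[, "start"] <= cds[j, "start"] &
                   ex[, "end"] >= cds[j, "end"])
      if (length(hit) != 1L) {
        note(m$transcript_id, "cds_without_exon",
             sprintf("CDS %d-%d", cds[j, "start"], cds[j, "end"]))
        good <- FALSE
      }
    }
    ok[i] <- good
  }
  kept <- models[ok]
  sig <- vapply(kept, function(m)
    paste(m$chrom, m$strand, paste(t(m$exons), collapse = ","),
          paste(t(m$cds), collapse = ","), sep = "|"), character(1))
  tids <- vapply(kept, `[[`, "", "transcript_id")
  o <- order(sig, tids)
  dup <- duplicated(sig[o])
  for (i in which(dup))
    note(tids[o][i], "duplicate_transcript",
         sprintf("duplicate of %s", tids[o][which(sig[o] == sig[o][i])[1L]]))
  keep_ids <- tids[o][!dup]
  clean <- kept[match(keep_ids, tids)]
  names(clean) <- keep_ids
  list(models = clean[order(names(clean))],
       issues = if (length(issues)) do.call(rbind, issues)
                else data.frame(transcript_id = character(),
                                issue = character(), detail = character(),
                                stringsAsFactors = FALSE))
}

#' Summarize protein comparisons
#'
#' Arithmetic means of identity, similarity and gap count over a
#' comparison table, in the layout of a cross-annotation summary.
#'
#' @param comparisons data.frame from [compare_proteins()].
#' @return list `mean_identity, mean_similarity, mean_gaps, n`.
#' @export
summarize_comparisons <- function(comparisons) {
  if (is.null(comparisons) || nrow(comparisons) == 0L)
    stop("no comparisons to summarize")
  list(mean_identity = mean(comparisons$identity),
       mean_similarity = mean(comparisons$similarity),
       mean_gaps = mean(comparisons$gap_positions),
       n = nrow(comparisons))
}

#' Full annotation QC: validate models then compare proteins
#'
#' @inheritParams compare_proteins
#' @return list with `comparisons`, `summary`, `issues` and the clean
#'   `models`.
#' @export
qc_gene_models <- function(models, genome, proteome, pairing,
                           thresholds = qc_thresholds(),
                           gene_classes = NULL) {
  v <- validate_gtf(models)
  cmp <- compare_proteins(v$models, genome, proteome, pairing, thresholds,
                          gene_classes)
  list(comparisons = cmp, summary = summarize_comparisons(cmp),
       issues = v$issues, models = v$models)
}
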