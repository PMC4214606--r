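#' Construct a gene model
#'
#' A gene model is one transcript: its exon intervals and CDS intervals
#' (with phase) on a single sequence and strand.  Exons must be sorted,
#' non-overlapping, and every CDS interval must be contained in exactly one
#' exon.
#'
#' @param transcript_id,gene_id,gene_name tokens.
#' @param gene_description free text.
#' @param chrom sequence (chromosome or scaffold) name.
#' @param strand `"+"` or `"-"`.
#' @param exons integer matrix with columns `start`, `end` (1-based
#'   inclusive), one row per exon.
#' @param cds integer matrix with columns `start`, `end`, `phase`
#'   (phase in 0..2 = bases to skip before the first complete codon);
#'   may have zero rows for non-coding transcripts.
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(transcript_id, gene_id, chrom, strand, exons,
                       cds = NULL, gene_name = gene_id,
                       gene_description = "") {
  exons <- interval_matrix(exons, c("start", "end"))
  if (is.null(cds)) cds <- matrix(integer(), 0L, 3L)
  cds <- interval_matrix(cds, c("start", "end", "phase"))
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  exons <- exons[order(exons[, "start"]), , drop = FALSE]
  if (nrow(exons) > 1L &&
      any(exons[-1L, "start"] <= exons[-nrow(exons), "end"]))
    stop("gene model '", transcript_id, "': overlapping exons")
  if (nrow(cds)) {
    cds <- cds[order(cds[, "start"]), , drop = FALSE]
    for (i in seq_len(nrow(cds))) {
      hit <- which(exons[, "start"] <= cds[i, "start"] &
                   exons[, "end"] >= cds[i, "end"])
      if (length(hit) != 1L)
        stop("gene model '", transcript_id,
             "': CDS interval not contained in exactly one exon")
    }
  }
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 gene_name = gene_name, gene_description = gene_description,
                 chrom = chrom, strand = strand, exons = exons, cds = cds),
            class = "gene_model")
}

interval_matrix <- function(x, nms) {
  m <- matrix(as.integer(as.matrix(x)), ncol = length(nms))
  colnames(m) <- nms
  m
}

#' @export
print.gene_model <- function(x, ...) {
  cat("gene_model ", x$transcript_id, " (", x$gene_id, ") ", x$chrom, ":",
      min(x$exons[, "start"]), "-", max(x$exons[, "end"]), " [", x$strand,
      "] ", nrow(x$exons), " exons, ", nrow(x$cds), " CDS\n", sep = "")
  invisible(x)
}

#' Read gene models from a GTF file
#'
#' Parses GTF2.2 via [rtracklayer::import()] and groups `exon` and `CDS`
#' features by `transcript_id`.  Attribute order is irrelevant.  Expected
#' attributes: `gene_id`, `transcript_id`, and optionally `gene_name` and
#' `gene_description`.
#'
#' @param path path to GTF file.
#' @return named list of [gene_model()] objects (names = transcript ids).
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df <- df[df$type %in% c("exon", "CDS"), , drop = FALSE]
  if (nrow(df) == 0L) stop("GTF '", path, "': no exon/CDS features")
  if (is.null(df$transcript_id) || anyNA(df$transcript_id))
    stop("GTF '", path, "': exon/CDS feature without transcript_id")
  if (is.null(df$gene_name)) df$gene_name <- df$gene_id
  if (is.null(df$gene_description)) df$gene_description <- ""
  df$gene_description[is.na(df$gene_description)] <- ""
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  models <- lapply(split(df, df$transcript_id), function(d) {
    strand <- unique(d$strand)
    if (length(strand) != 1L)
      stop("GTF '", path, "': transcript '", d$transcript_id[1L],
           "' mixes strands")
    chrom <- unique(d$seqnames)
    if (length(chrom) != 1L)
      stop("GTF '", path, "': transcript '", d$transcript_id[1L],
           "' spans multiple sequences")
    ex <- d[d$type == "exon", c("start", "end")]
    cd <- d[d$type == "CDS", c("start", "end", "phase")]
    cd$phase[is.na(cd$phase)] <- 0L
    gene_model(transcript_id = d$transcript_id[1L],
               gene_id = d$gene_id[1L],
               gene_name = d$gene_name[1L],
               gene_description = d$gene_description[1L],
               chrom = chrom, strand = strand,
               exons = as.matrix(ex),
               cds = if (nrow(cd)) as.matrix(cd) else NULL)
  })
  models[order(names(models))]
}

#' Write gene models to a GTF file
#'
#' Emits `exon` and `CDS` lines sorted by chromosome then start, with
#' `gene_id`, `transcript_id`, `gene_name` and `gene_description`
#' attributes.
#'
#' @param models list of [gene_model()] objects.
#' @param path output path.
#' @param source value for the GTF source column.
#' @export
write_gtf <- function(models, path, source = "scaftier") {
  rows <- lapply(models, function(m) {
    attrs <- sprintf(
      'gene_id "%s"; transcript_id "%s"; gene_name "%s"; gene_description "%s";',
      m$gene_id, m$transcript_id, m$gene_name, m$gene_description)
    ex <- data.frame(chrom = m$chrom, source = source, type = "exon",
                     start = m$exons[, "start"], end = m$exons[, "end"],
                     score = ".", strand = m$strand, phase = ".",
                     attrs = attrs, stringsAsFactors = FALSE)
    if (nrow(m$cds)) {
      cd <- data.frame(chrom = m$chrom, source = source, type = "CDS",
                       start = m$cds[, "start"], end = m$cds[, "end"],
                       score = ".", strand = m$strand,
                       phase = as.character(m$cds[, "phase"]),
                       attrs = attrs, stringsAsFactors = FALSE)
      ex <- rbind(ex, cd)
    }
    ex
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$chrom, tab$start, tab$end, tab$type), , drop = FALSE]
  writeLines(do.call(paste, c(unname(tab), sep = "\t")), path)
  invisible(path)
}
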