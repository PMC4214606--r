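#' Read a FASTA file
#'
#' Thin wrapper around [Biostrings::readBStringSet()] that normalizes and
#' validates records: record names are truncated to the first whitespace
#' token (the id), DNA sequences are upper-cased and checked against the
#' `ACGTN` alphabet, and duplicate or empty records raise located errors.
#'
#' @param path path to a (optionally gzipped) FASTA file.
#' @param type `"DNA"` (default) or `"AA"` for protein records.
#' @return a named [Biostrings::DNAStringSet] or [Biostrings::AAStringSet].
#' @export
read_fasta <- function(path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  raw <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(raw) == 0L)
    stop("malformed FASTA '", path, "': no records", call. = FALSE)
  ids <- sub("\\s.*$", "", names(raw))
  if (any(ids == ""))
    stop("malformed FASTA '", path, "': empty header at ",
         fasta_locate(path, which(ids == "")[1L]), call. = FALSE)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate id '", dup[1L], "' in '", path, "' at ",
         fasta_locate(path, which(ids == dup[1L])[2L]), call. = FALSE)
  seqs <- toupper(as.character(raw))
  if (any(nchar(seqs) == 0L))
    stop("empty sequence for id '", ids[which(nchar(seqs) == 0L)[1L]],
         "' in '", path, "' at ",
         fasta_locate(path, which(nchar(seqs) == 0L)[1L]), call. = FALSE)
  names(seqs) <- ids
  if (type == "DNA") {
    bad <- grepl("[^ACGTN]", seqs)
    if (any(bad))
      stop("non-ACGTN character in DNA record '", ids[which(bad)[1L]],
           "' in '", path, "'", call. = FALSE)
    Biostrings::DNAStringSet(seqs)
  } else {
    Biostrings::AAStringSet(seqs)
  }
}

## record index -> "line <n>" for error messages (scan only on failure)
fasta_locate <- function(path, record) {
  hdr <- grep("^>", readLines(path, warn = FALSE))
  if (record <= length(hdr)) paste0("line ", hdr[record]) else "end of file"
}

#' Write sequences to FASTA
#'
#' @param records named character vector or [Biostrings::XStringSet].
#' @param path output path.
#' @param line_width wrap width in characters.
#' @export
write_fasta <- function(records, path, line_width = 60L) {
  x <- as_xstringset(records)
  Biostrings::writeXStringSet(x, path, width = line_width)
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path path to a (optionally gzipped) FASTQ file.
#' @return a [Biostrings::QualityScaledDNAStringSet]; names are the first
#'   whitespace token of each read id.
#' @export
read_fastq <- function(path) {
  ## Biostrings warns when it drops (empty) metadata columns on subset
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' Write reads to FASTQ
#'
#' @param reads a [Biostrings::QualityScaledDNAStringSet].
#' @param path output path.
#' @export
write_fastq <- function(reads, path) {
  Biostrings::writeQualityScaledXStringSet(reads, path)
  invisible(path)
}

## ---- internal coercion helpers -------------------------------------------

as_seq_vector <- function(x) {
  if (is.character(x)) return(x)
  stats::setNames(as.character(x), names(x))
}

as_xstringset <- function(x) {
  if (methods::is(x, "XStringSet")) return(x)
  if (!is.character(x)) stop("expected character vector or XStringSet")
  if (all(!grepl("[^ACGTN]", x))) Biostrings::DNAStringSet(x)
  else Biostrings::AAStringSet(x)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
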