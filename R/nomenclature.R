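#' Load a chromosome nomenclature table
#'
#' The bundled table cross-references macaque chromosome labels across
#' seven naming systems: human (`H`), chimpanzee (`C`), gorilla (`G`),
#' orangutan (`O`), the macaque nomenclature used for chromosome builds
#' here (`M`, with `2a`/`2b` for the two macaque chromosomes homologous to
#' the arms of human chromosome 2), and two earlier macaque conventions
#' (`W`, `R`).
#'
#' @param path optional path to a TSV with columns `H C G O M W R`;
#'   defaults to the bundled table.
#' @return data.frame with one row per macaque chromosome.
#' @export
read_nomenclature <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "chromosome_nomenclature.tsv",
                        package = "scaftier", mustWork = TRUE)
  tab <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE)
  need <- c("H", "C", "G", "O", "M", "W", "R")
  if (!all(need %in% names(tab)))
    stop("nomenclature table must have columns ",
         paste(need, collapse = " "))
  if (anyDuplicated(tab$H))
    stop("nomenclature table: duplicate H labels")
  if (any(tab == "" | is.na(tab)))
    stop("nomenclature table: empty cells")
  tab
}

#' Translate a chromosome label between naming systems
#'
#' @param label chromosome label in the `from_col` system.
#' @param from_col,to_col column names of `table` (e.g. `"H"`, `"M"`).
#' @param table nomenclature table from [read_nomenclature()].
#' @return the corresponding label in the `to_col` system.
#' @examples
#' tab <- read_nomenclature()
#' map_chromosome_name("2p+", "H", "M", tab)  # "2a"
#' @export
map_chromosome_name <- function(label, from_col, to_col,
                                table = read_nomenclature()) {
  if (!from_col %in% names(table) || !to_col %in% names(table))
    stop("unknown nomenclature column '",
         setdiff(c(from_col, to_col), names(table))[1L], "'")
  i <- match(label, table[[from_col]])
  if (anyNA(i))
    stop("unknown chromosome label '", label[which(is.na(i))[1L]],
         "' in column ", from_col)
  table[[to_col]][i]
}
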