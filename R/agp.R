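#' Read an AGP v2.0 file
#'
#' Supports component (`W`) and scaffold-gap (`N`) rows.  On read the
#' tiling invariant is enforced: within each object, rows must cover
#' `1..object_end` consecutively with no overlap or hole, part numbers must
#' run from 1, and each row's object span must equal its component span
#' (W) or gap length (N).
#'
#' @param path path to AGP file.
#' @return a data.frame with columns `object, object_beg, object_end,
#'   part_number, component_type, component_id, component_beg,
#'   component_end, orientation, gap_length, gap_type, linkage` (gap
#'   columns are `NA` on W rows and vice versa).
#' @export
read_agp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 8L))
    stop("AGP '", path, "': fewer than 8 columns at line ",
         which(lengths(fields) < 8L)[1L], call. = FALSE)
  fields <- lapply(fields, function(f) c(f, rep("", 9L - length(f)))[1:9])
  m <- matrix(unlist(fields), ncol = 9L, byrow = TRUE)
  type <- m[, 5L]
  if (!all(type %in% c("W", "N")))
    stop("AGP '", path, "': unsupported component type '",
         setdiff(type, c("W", "N"))[1L], "'", call. = FALSE)
  w <- type == "W"
  component_beg <- component_end <- gap_length <- rep(NA_integer_, nrow(m))
  component_id <- orientation <- gap_type <- linkage <-
    rep(NA_character_, nrow(m))
  component_id[w] <- m[w, 6L]
  component_beg[w] <- as.integer(m[w, 7L])
  component_end[w] <- as.integer(m[w, 8L])
  orientation[w] <- m[w, 9L]
  gap_length[!w] <- as.integer(m[!w, 6L])
  gap_type[!w] <- m[!w, 7L]
  linkage[!w] <- m[!w, 8L]
  agp <- data.frame(
    object = m[, 1L],
    object_beg = as.integer(m[, 2L]), object_end = as.integer(m[, 3L]),
    part_number = as.integer(m[, 4L]), component_type = type,
    component_id = component_id, component_beg = component_beg,
    component_end = component_end, orientation = orientation,
    gap_length = gap_length, gap_type = gap_type, linkage = linkage,
    stringsAsFactors = FALSE
  )
  validate_agp(agp, path)
  agp
}

validate_agp <- function(agp, what = "AGP") {
  for (obj in unique(agp$object)) {
    rows <- agp[agp$object == obj, , drop = FALSE]
    rows <- rows[order(rows$part_number), , drop = FALSE]
    if (!identical(rows$part_number, seq_len(nrow(rows))))
      stop(what, ": object '", obj, "' part_numbers not consecutive from 1",
           call. = FALSE)
    expected_beg <- c(1L, rows$object_end[-nrow(rows)] + 1L)
    bad <- which(rows$object_beg != expected_beg)
    if (length(bad))
      stop(what, ": object '", obj, "' has an overlap or hole at coordinate ",
           expected_beg[bad[1L]], call. = FALSE)
    span <- rows$object_end - rows$object_beg + 1L
    comp_span <- ifelse(rows$component_type == "W",
                        rows$component_end - rows$component_beg + 1L,
                        rows$gap_length)
    if (any(span != comp_span))
      stop(what, ": object '", obj,
           "' row span does not match component span/gap length",
           call. = FALSE)
  }
  invisible(agp)
}

#' Write an AGP v2.0 file
#'
#' @param agp data.frame as returned by [read_agp()] or [build_agp()].
#' @param path output path.
#' @export
write_agp <- function(agp, path) {
  validate_agp(agp)
  w <- agp$component_type == "W"
  col6 <- ifelse(w, agp$component_id, agp$gap_length)
  col7 <- ifelse(w, agp$component_beg, agp$gap_type)
  col8 <- ifelse(w, agp$component_end, agp$linkage)
  col9 <- ifelse(w, agp$orientation, "")
  lines <- paste(agp$object, agp$object_beg, agp$object_end,
                 agp$part_number, agp$component_type,
                 col6, col7, col8, col9, sep = "\t")
  lines[!w] <- sub("\t$", "", lines[!w])
  writeLines(lines, path)
  invisible(path)
}
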