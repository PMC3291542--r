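#' Read BED3/BED6 annotation files
#'
#' BED is tab-separated and already 0-based half-open, so coordinates are
#' stored exactly as read. `mode = "intervals"` accepts 3 or more columns
#' and keeps the first three (plus name/strand when present);
#' `mode = "tss"` requires BED6 with a strand and converts each feature to
#' its strand-appropriate end: the TSS of a plus-strand feature is `start`,
#' of a minus-strand feature `end - 1`.
#'
#' Lines starting with `#`, `track` or `browser` are skipped. Every
#' validation failure reports its 1-based line number.
#'
#' @param path file path.
#' @param mode `"intervals"` (BED3+) or `"tss"` (BED6).
#' @return for `"intervals"` an interval data.frame; for `"tss"` a TSS
#'   data.frame (see [tss_set()]).
#' @export
read_bed <- function(path, mode = c("intervals", "tss")) {
  mode <- match.arg(mode)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  lines <- lines[keep]
  lineno <- which(keep)
  min_cols <- if (mode == "tss") 6L else 3L
  if (length(lines) == 0L) {
    if (mode == "tss")
      return(tss_set(character(), character(), numeric(), character()))
    return(genome_intervals(character(), numeric(), numeric()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < min_cols))
    stop(sprintf("line %d: expected at least %d tab-separated fields, found %d",
                 lineno[which(ncols < min_cols)[1]], min_cols,
                 min(ncols[ncols < min_cols])))
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) | end != floor(end))
  if (length(bad))
    stop(sprintf("line %d: non-integer coordinates", lineno[bad[1]]))
  bad <- which(start >= end)
  if (length(bad))
    stop(sprintf("line %d: start >= end", lineno[bad[1]]))
  name <- if (all(ncols >= 4L)) vapply(fields, `[[`, "", 4L) else NULL
  strand <- if (all(ncols >= 6L)) vapply(fields, `[[`, "", 6L) else NULL
  if (mode == "tss") {
    bad <- which(!strand %in% c("+", "-"))
    if (length(bad))
      stop(sprintf("line %d: missing or invalid strand in TSS mode", lineno[bad[1]]))
    pos <- ifelse(strand == "+", start, end - 1)
    return(tss_set(name, chrom, pos, strand))
  }
  if (!is.null(strand)) {
    bad <- which(!strand %in% c("+", "-", "*", "."))
    if (length(bad))
      stop(sprintf("line %d: invalid strand field", lineno[bad[1]]))
    strand[strand == "."] <- "*"
  }
  genome_intervals(chrom, start, end, strand = strand, name = name)
}

#' Write intervals as BED
#'
#' Emits a header comment line recording the provenance label and the
#' coordinate convention, followed by BED3 (or BED6 when the table carries
#' names and strands). Reading the file back with [read_bed()] returns the
#' records unchanged.
#'
#' @param x interval data.frame.
#' @param path output path.
#' @param provenance free-text label for the header comment.
#' @export
write_bed <- function(x, path, provenance = "cgimprint") {
  header <- sprintf("# %s; coordinates 0-based half-open (BED)", provenance)
  if (!is.null(x$strand)) {
    name <- if (is.null(x$name)) sprintf("feature_%d", seq_len(nrow(x))) else x$name
    body <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                    x$chrom, as.integer(x$start), as.integer(x$end), name, x$strand)
  } else if (!is.null(x$name)) {
    body <- sprintf("%s\t%d\t%d\t%s", x$chrom, as.integer(x$start),
                    as.integer(x$end), x$name)
  } else {
    body <- sprintf("%s\t%d\t%d", x$chrom, as.integer(x$start), as.integer(x$end))
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a TSS table as BED6
#'
#' The inverse of `read_bed(mode = "tss")`: each TSS becomes a 1 bp BED6
#' feature whose strand-appropriate end is the TSS position.
#'
#' @param tss TSS data.frame (see [tss_set()]).
#' @param path output path.
#' @param provenance header label.
#' @export
write_tss_bed <- function(tss, path, provenance = "cgimprint") {
  header <- sprintf("# %s; BED6, TSS at strand-appropriate feature end", provenance)
  body <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                  tss$chrom, as.integer(tss$pos), as.integer(tss$pos + 1),
                  tss$gene_id, tss$strand)
  writeLines(c(header, body), path)
  invisible(path)
}
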