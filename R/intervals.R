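#' Genomic interval tables
#'
#' All interval collections in this package are plain data frames in 0-based
#' half-open coordinates: column `start` is the first base of the feature,
#' `end` is one past the last, so the width is always `end - start`. This is
#' the native BED convention, and it makes the package's length arithmetic
#' agree with printed locus ranges of the form `chrN:A-B` whose stated sizes
#' equal `B - A`.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, `0 <= start < end`. Zero-length
#'   intervals are rejected.
#' @param strand optional vector over `"+"`, `"-"`, `"*"` (unstranded).
#' @param name optional feature names.
#' @return a data.frame with columns `chrom`, `start`, `end` and, when
#'   supplied, `name` and `strand`, sorted by (chrom, start).
#' @examples
#' genome_intervals("chr1", 100, 200)
#' @export
genome_intervals <- function(chrom, start, end, strand = NULL, name = NULL) {
  n <- length(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  stopifnot(length(start) == n, length(end) == n)
  if (any(is.na(chrom)) || any(is.na(start)) || any(is.na(end)))
    stop("intervals may not contain NA coordinates")
  if (any(start != floor(start)) || any(end != floor(end)))
    stop("interval coordinates must be integers")
  if (any(start < 0))
    stop("interval start must be >= 0")
  bad <- which(start >= end)
  if (length(bad))
    stop(sprintf("interval start must be < end (zero-length intervals rejected); first offender: %s:%d-%d",
                 chrom[bad[1]], start[bad[1]], end[bad[1]]))
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   stringsAsFactors = FALSE)
  if (!is.null(name)) df$name <- as.character(name)
  if (!is.null(strand)) {
    if (!all(strand %in% c("+", "-", "*")))
      stop("strand must be one of '+', '-', '*'")
    df$strand <- as.character(strand)
  }
  df[order(df$chrom, df$start), , drop = FALSE]
}

#' Interval widths
#'
#' @param x an interval data.frame (see [genome_intervals()]).
#' @return numeric vector of widths, `end - start`, always positive.
#' @export
interval_width <- function(x) x$end - x$start

#' Transcription start site tables
#'
#' A TSS is a stranded point. Orientation is mandatory because every
#' downstream classification ("upstream"/"downstream" of a CGI) is made in
#' transcript orientation.
#'
#' @param gene_id identifiers, one designated TSS per gene.
#' @param chrom chromosome names.
#' @param pos integer 0-based positions.
#' @param strand `"+"` or `"-"` (mandatory, no unstranded TSS).
#' @return data.frame with columns `gene_id`, `chrom`, `pos`, `strand`.
#' @export
tss_set <- function(gene_id, chrom, pos, strand) {
  n <- length(gene_id)
  if (length(chrom) == 1L) chrom <- rep(chrom, n)
  if (length(strand) == 1L) strand <- rep(strand, n)
  stopifnot(length(chrom) == n, length(pos) == n, length(strand) == n)
  pos <- as.numeric(pos)
  if (any(is.na(pos)) || any(pos != floor(pos)) || any(pos < 0))
    stop("TSS positions must be non-negative integers")
  if (!all(strand %in% c("+", "-")))
    stop("TSS strand must be '+' or '-'")
  data.frame(gene_id = as.character(gene_id), chrom = as.character(chrom),
             pos = pos, strand = as.character(strand),
             stringsAsFactors = FALSE)
}

#' Annotation set
#'
#' Bundles CGIs, designated gene TSSs and mask intervals (pseudogenes,
#' exons) with a provenance label. Lookups by chromosome are total: an
#' unknown chromosome yields an empty result, never an error.
#'
#' @param cgis interval data.frame of CpG islands.
#' @param genes TSS data.frame (see [tss_set()]).
#' @param masks interval data.frame of regions to exclude (may be empty).
#' @param provenance free-text source label, recorded in all writers.
#' @export
annotation_set <- function(cgis, genes, masks = genome_intervals(character(), numeric(), numeric()),
                           provenance = "unspecified") {
  structure(list(cgis = cgis, genes = genes, masks = masks,
                 provenance = provenance),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("Annotation set (", x$provenance, ")\n", sep = "")
  cat("  CGIs:  ", nrow(x$cgis), "\n")
  cat("  genes: ", nrow(x$genes), "\n")
  cat("  masks: ", nrow(x$masks), "\n")
  invisible(x)
}

#' Parse a printed locus string
#'
#' Interprets strings such as `"chr17:12934414-12935543"` under the
#' end-minus-start convention, so the width of the returned interval equals
#' the difference of the printed endpoints. Both plain hyphens and en/em
#' dashes are accepted as range separators, and internal whitespace is
#' ignored. The parser never adjusts inputs: a malformed string or a range
#' with `A >= B` is an error.
#'
#' @param text a coordinate string `"chrN:A-B"`.
#' @return one-row interval data.frame; width is `B - A`.
#' @examples
#' interval_width(parse_locus("chr17:12934414-12935543"))  # 1129
#' @export
parse_locus <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- gsub("[[:space:]]+", "", text)
  # en dash (–), em dash (—) and hyphen all separate the endpoints
  s <- gsub("[–—]", "-", s)
  m <- regmatches(s, regexec("^([A-Za-z0-9_.]+):([0-9]+)-([0-9]+)$", s))[[1]]
  if (length(m) != 4L) {
    bad <- if (!grepl(":", s)) s else sub("^[^:]*:", "", s)
    stop(sprintf("malformed locus string %s (offending token: '%s')",
                 sQuote(text), bad))
  }
  a <- as.numeric(m[3]); b <- as.numeric(m[4])
  if (a >= b)
    stop(sprintf("locus range requires A < B, got A = %s, B = %s", m[3], m[4]))
  genome_intervals(m[2], a, b)
}

#' Signed offset of a point in transcript orientation
#'
#' Offsets are measured from the anchor's oriented 5' edge: for a plus-strand
#' anchor that is `start`, for a minus-strand anchor it is `end - 1`.
#' Positive offsets point downstream in transcript orientation.
#'
#' @param point integer bp position.
#' @param anchor one-row interval data.frame on the same chromosome
#'   (chromosome checked when the anchor carries a `chrom` and `chrom_point`
#'   is given).
#' @param strand `"+"` or `"-"`.
#' @param chrom_point optional chromosome of the point, checked against the
#'   anchor's.
#' @return signed bp offset.
#' @export
oriented_offset <- function(point, anchor, strand, chrom_point = NULL) {
  stopifnot(nrow(anchor) == 1L, strand %in% c("+", "-"))
  if (!is.null(chrom_point) && chrom_point != anchor$chrom)
    stop(sprintf("chromosome mismatch: point on %s, anchor on %s",
                 chrom_point, anchor$chrom))
  if (strand == "+") point - anchor$start else anchor$end - 1 - point
}

#' Overlap test between two interval tables
#'
#' @param x,y interval data.frames.
#' @return logical vector along `x`: does row i of `x` overlap any row of
#'   `y` on the same chromosome?
#' @keywords internal
overlaps_any <- function(x, y) {
  if (nrow(x) == 0L) return(logical(0))
  if (nrow(y) == 0L) return(rep(FALSE, nrow(x)))
  out <- logical(nrow(x))
  for (ch in unique(x$chrom)) {
    xi <- which(x$chrom == ch)
    yy <- y[y$chrom == ch, , drop = FALSE]
    if (nrow(yy) == 0L) next
    for (i in xi) {
      out[i] <- any(x$start[i] < yy$end & yy$start < x$end[i])
    }
  }
  out
}
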