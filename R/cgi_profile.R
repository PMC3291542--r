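#' Extended CGI window with proportional flanks
#'
#' Each CpG island is extended by half its own length on both sides, so the
#' extended window is twice the island length and the island body occupies
#' its central half (relative coordinates [0.25, 0.75)). Odd island lengths
#' split the flanks floor/ceil, the upstream (left) flank taking the floor,
#' which keeps the total window length at exactly 2L. Windows are clipped at
#' the chromosome start; clipping is silent but flagged.
#'
#' @param cgi interval data.frame of CpG islands.
#' @return data.frame with columns `chrom`, `win_start`, `win_end`
#'   (clipped), `ideal_start` (possibly negative), `clipped`, plus the body
#'   coordinates `start`, `end`.
#' @export
extended_window <- function(cgi) {
  L <- interval_width(cgi)
  ideal_start <- cgi$start - floor(L / 2)
  win_end <- cgi$end + ceiling(L / 2)
  data.frame(chrom = cgi$chrom, start = cgi$start, end = cgi$end,
             win_start = pmax(ideal_start, 0), win_end = win_end,
             ideal_start = ideal_start, clipped = ideal_start < 0,
             stringsAsFactors = FALSE)
}

#' Associate TSSs with CpG islands
#'
#' A TSS is associated with a CGI when it falls inside the island's extended
#' window (island plus 50%-length flanks). When several extended windows
#' cover the TSS, the island whose body midpoint is nearest is chosen, ties
#' broken by lower start coordinate. The position within the window is
#' expressed as a relative coordinate in [0, 1) measured in transcript
#' orientation: for minus-strand genes the window is mirrored so that
#' "upstream" always means 5' of the gene. Relative coordinates in
#' [0.25, 0.75) are inside the island body, below 0.25 in the upstream
#' flank, at or above 0.75 in the downstream flank. The bin index is
#' `floor(100 * relative_coord)`, clamped to 99 so no TSS on the window edge
#' is dropped.
#'
#' For clipped windows the relative coordinate is computed over the ideal
#' (unclipped) window so the geometry of the bins is preserved; the
#' association record carries the `clipped` flag.
#'
#' @param tss TSS data.frame (see [tss_set()]).
#' @param cgis interval data.frame of CpG islands.
#' @param orient_by_strand mirror the window for minus-strand genes
#'   (default TRUE). With FALSE all genes are binned in genomic orientation.
#' @return data.frame with one row per TSS: `gene_id`, `relation`
#'   (`inside`, `upstream_flank`, `downstream_flank`, `unassociated`),
#'   `cgi_index` (row in the sorted `cgis` table, NA when unassociated),
#'   `relative_coord`, `bin_index`, `clipped`.
#' @export
associate_tss <- function(tss, cgis, orient_by_strand = TRUE) {
  win <- extended_window(cgis)
  n <- nrow(tss)
  relation <- rep("unassociated", n)
  cgi_index <- rep(NA_integer_, n)
  relative_coord <- rep(NA_real_, n)
  bin_index <- rep(NA_integer_, n)
  clipped <- rep(FALSE, n)
  for (ch in unique(tss$chrom)) {
    ti <- which(tss$chrom == ch)
    wi <- which(win$chrom == ch)
    if (length(wi) == 0L) next
    w <- win[wi, , drop = FALSE]
    ord <- order(w$win_start)
    w <- w[ord, , drop = FALSE]
    wi <- wi[ord]
    # windows may overlap: scan back from the last window starting <= pos,
    # stopping once the running max of window ends falls at or below pos
    cmax <- cummax(w$win_end)
    for (i in ti) {
      pos <- tss$pos[i]
      j <- findInterval(pos, w$win_start)
      hits <- integer(0)
      while (j >= 1L && cmax[j] > pos) {
        if (w$win_end[j] > pos && w$win_start[j] <= pos) hits <- c(hits, j)
        j <- j - 1L
      }
      if (length(hits) == 0L) next
      mid <- (w$start[hits] + w$end[hits]) / 2
      d <- abs(pos - mid)
      best <- hits[order(d, w$start[hits])][1L]
      Lw <- w$win_end[best] - w$ideal_start[best]
      rel <- if (orient_by_strand && tss$strand[i] == "-") {
        (w$win_end[best] - 1 - pos) / Lw
      } else {
        (pos - w$ideal_start[best]) / Lw
      }
      relation[i] <- if (rel >= 0.25 && rel < 0.75) "inside"
                     else if (rel < 0.25) "upstream_flank"
                     else "downstream_flank"
      cgi_index[i] <- wi[best]
      relative_coord[i] <- rel
      bin_index[i] <- min(floor(100 * rel), 99)
      clipped[i] <- w$clipped[best]
    }
  }
  data.frame(gene_id = tss$gene_id, relation = relation, cgi_index = cgi_index,
             relative_coord = relative_coord, bin_index = bin_index,
             clipped = clipped, stringsAsFactors = FALSE)
}

#' Build a 100-bin TSS metagene profile around CpG islands
#'
#' Counts designated TSSs per bin of the extended CGI window (island plus
#' 50%-length flanks, 100 equal bins) and summarises the association
#' fractions: the percentage of all genes associated with any CGI, and of
#' the associated genes the percentages falling inside the island body or in
#' the upstream/downstream flank.
#'
#' @inheritParams associate_tss
#' @return an object of class `metagene_profile`: list with `bins` (100
#'   counts), `n_genes_total`, `n_associated`, `fractions` (percent:
#'   `associated` of all genes; `inside`, `upstream`, `downstream` of
#'   associated genes; all NA when the relevant denominator is 0) and the
#'   per-gene `associations` table for audit.
#' @export
build_profile <- function(tss, cgis, orient_by_strand = TRUE) {
  assoc <- associate_tss(tss, cgis, orient_by_strand = orient_by_strand)
  bins <- integer(100)
  hit <- !is.na(assoc$bin_index)
  if (any(hit)) {
    tab <- tabulate(assoc$bin_index[hit] + 1L, nbins = 100L)
    bins <- as.integer(tab)
  }
  n_total <- nrow(tss)
  n_assoc <- sum(hit)
  frac <- c(associated = NA_real_, inside = NA_real_,
            upstream = NA_real_, downstream = NA_real_)
  if (n_total > 0L) frac["associated"] <- 100 * n_assoc / n_total
  if (n_assoc > 0L) {
    frac["inside"] <- 100 * sum(assoc$relation == "inside") / n_assoc
    frac["upstream"] <- 100 * sum(assoc$relation == "upstream_flank") / n_assoc
    frac["downstream"] <- 100 * sum(assoc$relation == "downstream_flank") / n_assoc
  }
  structure(list(bins = bins, n_genes_total = n_total, n_associated = n_assoc,
                 fractions = frac, associations = assoc),
            class = "metagene_profile")
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat("TSS/CGI metagene profile (100 bins)\n")
  cat(sprintf("  genes: %d total, %d associated with a CGI", x$n_genes_total,
              x$n_associated))
  if (!is.na(x$fractions["associated"]))
    cat(sprintf(" (%.1f%%)", x$fractions["associated"]))
  cat("\n")
  if (!is.na(x$fractions["inside"]))
    cat(sprintf("  of associated: %.1f%% inside, %.1f%% upstream, %.1f%% downstream\n",
                x$fractions["inside"], x$fractions["upstream"],
                x$fractions["downstream"]))
  invisible(x)
}

#' @export
summary.metagene_profile <- function(object, ...) {
  print(object)
  cat("  peak bin:", which.max(object$bins) - 1L,
      "(", max(object$bins), "TSSs )\n")
  invisible(object)
}

#' @export
plot.metagene_profile <- function(x, ...) {
  graphics::barplot(x$bins, names.arg = NULL, border = NA, space = 0,
                    xlab = "relative position (bin)", ylab = "TSS count",
                    main = "TSSs relative to CGI (central half = island body)",
                    ...)
  graphics::abline(v = c(25, 75), lty = 2)
  invisible(x)
}

#' Write a metagene profile as TSV
#'
#' 100 rows of (bin_index, count) preceded by a header block carrying the
#' four association fractions.
#'
#' @param x a `metagene_profile`.
#' @param path output path.
#' @export
write_profile_tsv <- function(x, path) {
  hdr <- c(sprintf("# n_genes_total\t%d", x$n_genes_total),
           sprintf("# n_associated\t%d", x$n_associated),
           sprintf("# pct_%s\t%s", names(x$fractions),
                   formatC(x$fractions, digits = 6, format = "g")),
           "bin_index\tcount")
  body <- sprintf("%d\t%d", 0:99, x$bins)
  writeLines(c(hdr, body), path)
  invisible(path)
}
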