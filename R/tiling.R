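#' One-step Tukey biweight location estimate
#'
#' The classical robust location estimate used for array summarisation:
#' values are centred on their median and scaled by the (unscaled) median
#' absolute deviation; observations receive weights `(1 - u^2)^2` for
#' `|u| < 1` and zero otherwise, with `u = (x - median) / (c * MAD + eps)`,
#' and the weighted mean is returned. One step, not iterated. A degenerate
#' MAD of 0 returns the median.
#'
#' @param values non-empty numeric vector.
#' @param c tuning constant (default 5, the array convention).
#' @param eps small constant guarding the scale (default 1e-4).
#' @return the biweight location (scalar).
#' @export
tukey_biweight_location <- function(values, c = 5, eps = 1e-4) {
  if (length(values) == 0L) stop("empty input")
  values <- as.numeric(values)
  if (anyNA(values)) stop("NA values not allowed")
  med <- stats::median(values)
  s <- stats::median(abs(values - med))  # unscaled MAD
  if (s == 0) return(med)
  u <- (values - med) / (c * s + eps)
  w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
  sum(w * values) / sum(w)
}

#' Per-probe relative signal intensities
#'
#' Each probe's cDNA/genomic-DNA fluorescence ratio is computed, the ratio
#' vector is Tukey-biweight normalised (centred on its biweight location in
#' log space, then back-transformed), and the result is rescaled by its
#' arithmetic mean so that the mean relative intensity over the analysed
#' region is exactly 1. Probes with zero genomic signal must be removed
#' beforehand (see [qc_probes()]).
#'
#' @param probes data.frame with numeric columns `cdna` and `gdna`
#'   (`gdna > 0`).
#' @param c,eps biweight parameters, see [tukey_biweight_location()].
#' @return numeric vector of relative intensities, mean 1 (to 1e-9). If all
#'   cDNA signals are zero the values are all zero and a warning is issued.
#' @export
relative_intensity <- function(probes, c = 5, eps = 1e-4) {
  if (nrow(probes) == 0L) stop("no probes")
  if (any(probes$gdna <= 0))
    stop("probes with non-positive genomic signal must be dropped before analysis (qc_probes)")
  r <- probes$cdna / probes$gdna
  if (all(r == 0)) {
    warning("all cDNA signals are zero over the region; relative values set to 0")
    return(rep(0, length(r)))
  }
  centre <- tukey_biweight_location(log(r[r > 0]), c = c, eps = eps)
  v <- r / exp(centre)
  v / mean(v)
}

#' Drop probes with no genomic-DNA signal
#'
#' @param probes probe data.frame with columns `cdna`, `gdna`.
#' @return the probes with `gdna > 0`; the number removed is reported via
#'   message.
#' @export
qc_probes <- function(probes) {
  bad <- probes$gdna <= 0 | is.na(probes$gdna) | is.na(probes$cdna)
  if (any(bad))
    message(sprintf("dropped %d probe(s) with missing or zero genomic signal", sum(bad)))
  probes[!bad, , drop = FALSE]
}

#' Remove probes overlapping mask intervals
#'
#' Used to exclude pseudogenes and other repetitive features from the
#' tiling-array analysis. A probe is removed when its interval overlaps any
#' mask on the same chromosome.
#'
#' @param probes probe data.frame with columns `chrom`, `start`, `end`.
#' @param masks interval data.frame.
#' @return the unmasked probes; removals are reported via message, and a
#'   warning is raised if nothing survives.
#' @export
apply_masks <- function(probes, masks) {
  if (is.null(masks) || nrow(masks) == 0L) return(probes)
  hit <- overlaps_any(probes, masks)
  if (any(hit))
    message(sprintf("masked out %d probe(s) overlapping %d mask interval(s)",
                    sum(hit), nrow(masks)))
  out <- probes[!hit, , drop = FALSE]
  if (nrow(out) == 0L) warning("all probes removed by masks")
  out
}

#' Smooth relative intensities into displayed points
#'
#' Overlapping windows of `tiles_per_window` consecutive probes (step one
#' tile) are averaged; the window means are then grouped into consecutive
#' disjoint blocks of `windows_per_point`, and each displayed point reports
#' the mean and sample standard deviation of its block of window means. The
#' point position is the central probe position of its block. A trailing
#' block with fewer windows is emitted with its actual `n_windows` and
#' flagged `partial`, never silently averaged as full.
#'
#' @param positions probe positions (bp), strictly increasing.
#' @param values per-probe relative intensities (see
#'   [relative_intensity()]).
#' @param tiles_per_window probes per overlapping window (default 9).
#' @param windows_per_point window means per displayed point (default 20).
#' @return an object of class `ri_profile`: data.frame with columns
#'   `position`, `mean`, `sd`, `n_windows`, `partial`.
#' @export
smooth_profile <- function(positions, values, tiles_per_window = 9,
                           windows_per_point = 20) {
  n <- length(values)
  stopifnot(length(positions) == n)
  if (is.unsorted(positions, strictly = TRUE))
    stop("probe positions must be strictly increasing")
  if (n < tiles_per_window)
    stop(sprintf("need at least %d probes, got %d", tiles_per_window, n))
  cs <- c(0, cumsum(values))
  n_win <- n - tiles_per_window + 1L
  wmean <- (cs[(tiles_per_window + 1):(n + 1)] - cs[1:n_win]) / tiles_per_window
  blocks <- split(seq_len(n_win), (seq_len(n_win) - 1L) %/% windows_per_point)
  pts <- lapply(blocks, function(idx) {
    k <- length(idx)
    # block spans probes idx[1] .. idx[k] + tiles_per_window - 1
    first <- idx[1L]; last <- idx[k] + tiles_per_window - 1L
    centre <- floor((first + last) / 2)
    data.frame(position = positions[centre],
               mean = mean(wmean[idx]),
               sd = if (k > 1L) stats::sd(wmean[idx]) else 0,
               n_windows = k,
               partial = k < windows_per_point)
  })
  out <- do.call(rbind, pts)
  rownames(out) <- NULL
  class(out) <- c("ri_profile", "data.frame")
  out
}

#' @export
plot.ri_profile <- function(x, ...) {
  graphics::plot(x$position, x$mean, type = "b", pch = 16,
                 xlab = "position (bp)", ylab = "relative intensity", ...)
  up <- x$mean + x$sd; lo <- x$mean - x$sd
  ok <- x$sd > 0
  graphics::arrows(x$position[ok], lo[ok], x$position[ok], up[ok],
                   angle = 90, code = 3, length = 0.03)
  invisible(x)
}

#' Segment the analysed region in transcript-oriented coordinates
#'
#' The displayed locus splits into three adjacent parts: a region specific
#' to the 3' end of the overlapping sense gene (Igf2r), the sense/antisense
#' transcriptional overlap, and the region specific to the 3' end of the
#' antisense macro ncRNA. Coordinates are oriented bp downstream of the
#' designated ncRNA TSS (the origin), so the sense-specific part lies at
#' negative coordinates and the overlap conventionally starts at 0.
#'
#' @param igf2r_end oriented bp of the sense transcript's 3' end
#'   (the left edge of the region; must be `< overlap_start`).
#' @param overlap_end oriented bp where the transcriptional overlap ends and
#'   the ncRNA-specific part begins (default geometry: 28 kb).
#' @param transcript_end oriented bp of the ncRNA 3' end (default geometry:
#'   118 kb).
#' @param overlap_start boundary between the sense-specific part and the
#'   overlap; defaults to 0, the ncRNA TSS.
#' @param chrom chromosome label used for the interval table.
#' @return a `region_segmentation`: list of three one-row interval
#'   data.frames `igf2r_specific`, `overlap`, `transcript_specific` that are
#'   disjoint, adjacent and tile the region. Stored as oriented coordinates
#'   in columns `start`/`end` (which may be negative, unlike genomic
#'   intervals).
#' @export
segment_region <- function(igf2r_end, overlap_end, transcript_end,
                           overlap_start = 0, chrom = "oriented") {
  b <- c(igf2r_end, overlap_start, overlap_end, transcript_end)
  if (any(diff(b) <= 0))
    stop("segment boundaries must be strictly increasing: igf2r_end < overlap_start < overlap_end < transcript_end")
  seg <- function(a, z) data.frame(chrom = chrom, start = a, end = z,
                                   stringsAsFactors = FALSE)
  structure(list(igf2r_specific = seg(igf2r_end, overlap_start),
                 overlap = seg(overlap_start, overlap_end),
                 transcript_specific = seg(overlap_end, transcript_end)),
            class = "region_segmentation")
}

#' @export
print.region_segmentation <- function(x, ...) {
  cat("Region segmentation (oriented bp from ncRNA TSS)\n")
  for (nm in names(x))
    cat(sprintf("  %-20s [%g, %g)\n", nm, x[[nm]]$start, x[[nm]]$end))
  invisible(x)
}

#' Estimate background signal from profile points
#'
#' Returns the background level as the mean of the point means in the
#' interval, and the background spread as the pooled standard deviation of
#' the window means within those points — the same quantity the profile
#' displays as its error bars, and therefore the band against which a signal
#' is visually judged "absent". (The spread of the point means themselves is
#' several-fold narrower, and a threshold placed a fixed number of those SDs
#' above background is exceeded by a constant fraction of background points
#' whatever the noise level, which makes consecutive-point rules fragile.)
#'
#' @param profile an `ri_profile`.
#' @param from,to oriented positions delimiting points outside annotated
#'   transcription.
#' @return list with `mean`, `sd` (pooled window-mean SD) and `n_points`.
#' @export
estimate_background <- function(profile, from, to) {
  sel <- profile$position >= from & profile$position < to
  if (sum(sel) < 2L)
    stop("need at least 2 profile points in the background interval")
  list(mean = mean(profile$mean[sel]),
       sd = sqrt(mean(profile$sd[sel]^2)),
       n_points = sum(sel))
}

#' Call transcript reduction and absence boundaries
#'
#' Compares a mutant relative-intensity profile with its wildtype control
#' over the transcript-specific segment. The reduction boundary is the
#' oriented position of the first point at which the mutant mean falls below
#' `(1 - delta)` times the wildtype mean for `k` consecutive points; the
#' absence boundary is the first point at which the mutant mean drops to the
#' background level (`background$mean + z * background$sd`) for `k`
#' consecutive points. Either field is absent (NA) when no such run exists.
#' The criterion parameters are recorded in the call for reproducibility.
#'
#' Because each profile is normalised to its own region mean, a truncated
#' transcript inflates the mutant's relative scale (less total signal in the
#' region makes every remaining point relatively brighter). When
#' `calibration` is given, the mutant profile (and a supplied background,
#' which is on the mutant's scale) is therefore rescaled by the ratio of
#' wildtype to mutant means over that segment before thresholding; the
#' natural choice is a segment where the genotypes are expected to agree,
#' such as the sense-gene-specific part of the locus.
#'
#' @param mutant,wildtype `ri_profile` objects sharing point positions over
#'   the transcript-specific segment (no resampling is attempted; mismatched
#'   grids are an error).
#' @param background list with `mean` and `sd` on the mutant profile's
#'   scale, e.g. [estimate_background()] on the mutant's points outside
#'   annotated transcription.
#' @param segment one-row interval (oriented coordinates) delimiting the
#'   transcript-specific part, e.g.
#'   `segment_region(...)$transcript_specific`; NULL uses all shared points.
#' @param calibration optional one-row interval over which the two profiles
#'   are expected to agree; used to rescale the mutant (and background)
#'   onto the wildtype's scale. NULL (default) compares the profiles as
#'   given.
#' @param delta fractional reduction threshold (default 0.25).
#' @param k consecutive points required (default 3).
#' @param z background multiplier (default 2).
#' @return an `extent_call`: list with `reduction_start`, `absence_start`
#'   (oriented bp or NA), `criterion_params` and the applied
#'   `calibration_factor` (1 when no calibration requested).
#' @export
call_extent <- function(mutant, wildtype, background, segment = NULL,
                        calibration = NULL, delta = 0.25, k = 3, z = 2) {
  m <- as.data.frame(mutant); w <- as.data.frame(wildtype)
  scale <- 1
  if (!is.null(calibration)) {
    msel <- m$position >= calibration$start & m$position < calibration$end
    wsel <- w$position >= calibration$start & w$position < calibration$end
    if (sum(msel) < 1L || sum(wsel) < 1L)
      stop("no profile points in the calibration segment")
    scale <- mean(w$mean[wsel]) / mean(m$mean[msel])
    m$mean <- m$mean * scale
    background <- list(mean = background$mean * scale,
                       sd = background$sd * scale)
  }
  if (!is.null(segment)) {
    m <- m[m$position >= segment$start & m$position < segment$end, , drop = FALSE]
    w <- w[w$position >= segment$start & w$position < segment$end, , drop = FALSE]
  }
  if (nrow(m) != nrow(w) || any(m$position != w$position))
    stop("mutant and wildtype profiles must share point positions (no resampling attempted)")
  first_run <- function(cond) {
    r <- rle(cond)
    ends <- cumsum(r$lengths)
    i <- which(r$values & r$lengths >= k)
    if (length(i) == 0L) return(NA_real_)
    m$position[ends[i[1L]] - r$lengths[i[1L]] + 1L]
  }
  reduction_start <- first_run(m$mean < (1 - delta) * w$mean)
  absence_start <- first_run(m$mean <= background$mean + z * background$sd)
  if (!is.na(reduction_start) && !is.na(absence_start) &&
      reduction_start > absence_start)
    reduction_start <- absence_start
  structure(list(reduction_start = reduction_start,
                 absence_start = absence_start,
                 criterion_params = list(delta = delta, k = k, z = z),
                 calibration_factor = scale),
            class = "extent_call")
}

#' @export
print.extent_call <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "not called" else sprintf("%g bp", v)
  cat("Transcript extent call\n")
  cat("  reduction from:", fmt(x$reduction_start), "\n")
  cat("  absence from:  ", fmt(x$absence_start), "\n")
  cat(sprintf("  criterion: delta = %g, k = %d, z = %g\n",
              x$criterion_params$delta, x$criterion_params$k,
              x$criterion_params$z))
  invisible(x)
}

#' Strand-specific read-count log2 ratios in fixed windows
#'
#' Tiles the region left-to-right with non-overlapping windows (default
#' 3.2 kb), counts reads mapping to the forward and reverse strand in each
#' window and reports `log2((fwd + alpha) / (rev + alpha))` with pseudocount
#' `alpha` (default 1). Windows overlapping a mask are flagged `masked` and
#' carry no ratio; windows with zero reads on both strands are likewise
#' reported without a ratio.
#'
#' @param reads data.frame with columns `chrom`, `start` (0-based read
#'   position) and `strand` (`"+"` forward / `"-"` reverse), e.g. from
#'   `read_bed(..., mode = "intervals")` on a BED6 file.
#' @param region one-row interval data.frame to tile.
#' @param window_size window width in bp (default 3200; must be positive).
#' @param masks interval data.frame of excluded features (exons,
#'   pseudogenes), or NULL.
#' @param alpha pseudocount (default 1).
#' @return data.frame with columns `chrom`, `start`, `end`, `fwd_count`,
#'   `rev_count`, `log2_ratio` (NA when masked or empty), `masked`.
#' @export
strand_log_ratio <- function(reads, region, window_size = 3200, masks = NULL,
                             alpha = 1) {
  if (window_size <= 0) stop("window_size must be positive")
  stopifnot(nrow(region) == 1L)
  starts <- seq(region$start, region$end - 1, by = window_size)
  wins <- data.frame(chrom = region$chrom, start = starts,
                     end = pmin(starts + window_size, region$end),
                     stringsAsFactors = FALSE)
  rr <- reads[reads$chrom == region$chrom &
              reads$start >= region$start & reads$start < region$end, ,
              drop = FALSE]
  idx <- findInterval(rr$start, starts)
  fwd <- tabulate(idx[rr$strand == "+"], nbins = nrow(wins))
  rev <- tabulate(idx[rr$strand == "-"], nbins = nrow(wins))
  masked <- if (is.null(masks)) rep(FALSE, nrow(wins)) else overlaps_any(wins, masks)
  ratio <- log2((fwd + alpha) / (rev + alpha))
  ratio[masked] <- NA_real_
  empty <- fwd == 0 & rev == 0
  ratio[empty] <- NA_real_
  data.frame(chrom = wins$chrom, start = wins$start, end = wins$end,
             fwd_count = fwd, rev_count = rev, log2_ratio = ratio,
             masked = masked | empty, stringsAsFactors = FALSE)
}
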