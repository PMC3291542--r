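#' Seeded synthetic-data generators
#'
#' Each `sim_*` generator produces inputs with the statistical structure the
#' corresponding analysis stage assumes, together with a `truth` record of
#' the generating parameters, so parameter recovery is testable without any
#' external data. All generators are deterministic given `(seed, arguments)`:
#' they pin the RNG to Mersenne-Twister with the given seed and restore the
#' caller's RNG state on exit. The seed is recorded in every truth record.
#'
#' @name simulators
#' @keywords internal
NULL

with_sim_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

#' Simulate CGI and TSS annotations with known association classes
#'
#' Places one non-overlapping CpG island per associated gene on a synthetic
#' chromosome (islands spaced so their extended windows cannot overlap) and
#' draws each gene's TSS uniformly within the sub-window of its requested
#' class: upstream flank (relative coordinate [0, 0.25)), island body
#' ([0.25, 0.75)) or downstream flank ([0.75, 1)), in transcript orientation
#' with a random strand. Unassociated genes are placed in the gaps, outside
#' every extended window.
#'
#' @param n_genes number of genes.
#' @param fractions named numeric vector over `inside`, `upstream`,
#'   `downstream`, `unassociated`, summing to 1. Defaults mirror a
#'   genome-scale survey: 57% of genes CGI-associated, of which 88.5%
#'   inside, 8.7% upstream and 2.8% downstream.
#' @param cgi_length_range min/max island length in bp (uniform draw).
#' @param gap bp of clear space flanking every extended window (default
#'   10000; must be positive so association is unambiguous).
#' @param chrom synthetic chromosome name.
#' @param seed RNG seed.
#' @return list with `cgis` (interval data.frame), `genes` (TSS data.frame)
#'   and `truth` (per-gene class, requested fractions, seed).
#' @export
sim_annotation <- function(n_genes,
                           fractions = c(inside = 0.57 * 0.885,
                                         upstream = 0.57 * 0.087,
                                         downstream = 0.57 * 0.028,
                                         unassociated = 0.43),
                           cgi_length_range = c(200, 2000),
                           gap = 10000, chrom = "chrS", seed = 1) {
  stopifnot(all(c("inside", "upstream", "downstream", "unassociated") %in%
                names(fractions)))
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  if (gap <= 0) stop("gap must be positive")
  if (n_genes == 0L) {
    return(list(cgis = genome_intervals(character(), numeric(), numeric()),
                genes = tss_set(character(), character(), numeric(), character()),
                truth = list(classes = character(), fractions = fractions,
                             seed = seed)))
  }
  with_sim_seed(seed, {
    classes <- sample(names(fractions), n_genes, replace = TRUE,
                      prob = fractions)
    strands <- sample(c("+", "-"), n_genes, replace = TRUE)
    L <- round(stats::runif(n_genes, cgi_length_range[1], cgi_length_range[2]))
    # lay out one window slot per gene: [cursor, cursor + 2L) then a gap
    slot <- 2 * L + gap
    win_start <- gap + c(0, cumsum(slot[-n_genes]))
    cgi_start <- win_start + floor(L / 2)
    win_end <- win_start + 2 * L
    pos <- numeric(n_genes)
    for (i in seq_len(n_genes)) {
      Lw <- 2 * L[i]
      q1 <- ceiling(0.25 * Lw); q3 <- ceiling(0.75 * Lw)
      u <- switch(classes[i],
                  upstream = sample.int(q1, 1L) - 1L,
                  inside = q1 + sample.int(q3 - q1, 1L) - 1L,
                  downstream = q3 + sample.int(Lw - q3, 1L) - 1L,
                  unassociated = NA_integer_)
      if (classes[i] == "unassociated") {
        pos[i] <- win_end[i] + floor(gap / 2)  # mid-gap, outside every window
      } else if (strands[i] == "+") {
        pos[i] <- win_start[i] + u
      } else {
        pos[i] <- win_end[i] - 1 - u
      }
    }
    keep <- classes != "unassociated"
    cgis <- genome_intervals(rep(chrom, sum(keep)), cgi_start[keep],
                             cgi_start[keep] + L[keep])
    genes <- tss_set(sprintf("g%04d", seq_len(n_genes)), rep(chrom, n_genes),
                     pos, strands)
    list(cgis = cgis, genes = genes,
         truth = list(classes = classes, fractions = fractions, seed = seed))
  })
}

#' Decline factor of a truncated transcript
#'
#' Signal is at full level before `decline_start`, then drops by
#' `initial_drop` and declines to exactly zero at `truncation` (linear by
#' default; the exponential shape falls with time constant
#' `(truncation - decline_start) / 4`, rescaled to hit zero at truncation).
#' The initial drop reflects how such truncation phenotypes read out on an
#' array: the reduction is visible immediately at the boundary, then fades
#' gradually rather than stepwise.
#'
#' @param x oriented positions (bp).
#' @param decline_start,truncation oriented bp; both NULL means full length.
#' @param initial_drop fractional step at `decline_start` (default 0.35).
#' @param shape `"linear"` or `"exponential"`.
#' @return decline factors in [0, 1].
#' @export
decline_factor <- function(x, decline_start, truncation, initial_drop = 0.35,
                           shape = c("linear", "exponential")) {
  shape <- match.arg(shape)
  if (is.null(decline_start) || is.null(truncation)) return(rep(1, length(x)))
  if (decline_start > truncation) stop("decline_start must be <= truncation")
  f <- rep(1, length(x))
  inside <- x >= decline_start & x < truncation
  s <- (x[inside] - decline_start) / (truncation - decline_start)
  g <- if (shape == "linear") 1 - s else {
    e <- exp(-4 * s)
    (e - exp(-4)) / (1 - exp(-4))
  }
  f[inside] <- (1 - initial_drop) * g
  f[x >= truncation] <- 0
  f
}

#' Simulate a tiling-array probe table over the locus
#'
#' Probes of `probe_len` bp spaced every `spacing` bp tile the oriented
#' region. The cDNA channel is the sum of a baseline, the sense (Igf2r-like)
#' transcript over `[region_start, overlap_end)`, and the antisense macro
#' ncRNA over `[0, transcript_end)` scaled by `initiation_scale` and by the
#' decline factor of an optional truncation (see [decline_factor()]); the
#' genomic-DNA channel is constant. Both channels carry multiplicative
#' lognormal noise (`noise_sd` is the log-scale standard deviation, so 0.1
#' means roughly 10% noise).
#'
#' Coordinates are oriented bp downstream of the ncRNA TSS; the probe table
#' uses them directly as `start`/`end` on a synthetic chromosome (negative
#' starts are permitted here because the axis is oriented, not genomic).
#'
#' @param region_start,region_end oriented extent of the array (defaults
#'   -62 kb to 130 kb, leaving untranscribed background beyond the 118 kb
#'   transcript end for background estimation).
#' @param probe_len,spacing probe geometry (defaults 50 and 100 bp).
#' @param overlap_end end of the sense/antisense overlap (default 28 kb).
#' @param transcript_end ncRNA 3' end (default 118 kb).
#' @param igf2r_level,airn_level,baseline signal levels (arbitrary units).
#' @param initiation_scale global scaling of the ncRNA contribution
#'   (emulates reduced initiation; default 1).
#' @param decline_start,truncation truncation truth (oriented bp) or NULL
#'   for a full-length transcript.
#' @param initial_drop,decline_shape see [decline_factor()].
#' @param noise_sd log-scale noise SD (default 0.1).
#' @param gdna_level genomic channel level (default 100).
#' @param chrom chromosome label.
#' @param seed RNG seed.
#' @return list with `probes` (data.frame `chrom`, `start`, `end`, `cdna`,
#'   `gdna`) and `truth` (all generating parameters plus the seed).
#' @export
sim_tiling <- function(region_start = -62000, region_end = 130000,
                       probe_len = 50, spacing = 100,
                       overlap_end = 28000, transcript_end = 118000,
                       igf2r_level = 1, airn_level = 1.3, baseline = 0.2,
                       initiation_scale = 1,
                       decline_start = NULL, truncation = NULL,
                       initial_drop = 0.35,
                       decline_shape = c("linear", "exponential"),
                       noise_sd = 0.1, gdna_level = 100,
                       chrom = "oriented", seed = 1) {
  decline_shape <- match.arg(decline_shape)
  if (!is.null(truncation) &&
      (truncation <= overlap_end || truncation > transcript_end))
    stop("truncation must lie within the transcript-specific segment")
  with_sim_seed(seed, {
    start <- seq(region_start, region_end - probe_len, by = spacing)
    mid <- start + probe_len / 2
    airn <- airn_level * initiation_scale *
      decline_factor(mid, decline_start, truncation, initial_drop,
                     decline_shape) * (mid >= 0 & mid < transcript_end)
    igf2r <- igf2r_level * (mid >= region_start & mid < overlap_end)
    signal <- baseline + airn + igf2r
    n <- length(start)
    cdna <- signal * exp(stats::rnorm(n, 0, noise_sd))
    gdna <- gdna_level * exp(stats::rnorm(n, 0, noise_sd))
    list(probes = data.frame(chrom = chrom, start = start,
                             end = start + probe_len,
                             cdna = cdna, gdna = gdna,
                             stringsAsFactors = FALSE),
         truth = list(overlap_end = overlap_end,
                      transcript_end = transcript_end,
                      igf2r_level = igf2r_level, airn_level = airn_level,
                      baseline = baseline, initiation_scale = initiation_scale,
                      decline_start = decline_start, truncation = truncation,
                      initial_drop = initial_drop, decline_shape = decline_shape,
                      noise_sd = noise_sd, seed = seed))
  })
}

#' Simulate stranded reads over segmented expression rates
#'
#' Reads are distributed multinomially over the segments with probability
#' proportional to (forward rate + reverse rate) x segment length, placed
#' uniformly within their segment, and assigned a strand with probability
#' forward rate / (forward + reverse) per segment.
#'
#' @param rates data.frame with columns `start`, `end` (oriented bp) and
#'   non-negative `fwd_rate`, `rev_rate`; not all rates may be zero.
#' @param n_reads number of reads (>= 0).
#' @param chrom chromosome label.
#' @param read_len read length in bp for the BED-style end column.
#' @param seed RNG seed.
#' @return list with `reads` (data.frame `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`) and `truth` (rates table plus seed).
#' @export
sim_stranded_reads <- function(rates, n_reads, chrom = "oriented",
                               read_len = 50, seed = 1) {
  if (n_reads < 0) stop("n_reads must be >= 0")
  tot <- rates$fwd_rate + rates$rev_rate
  if (any(tot < 0) || all(tot == 0)) stop("rates must be >= 0 and not all zero")
  with_sim_seed(seed, {
    w <- tot * (rates$end - rates$start)
    seg <- sample.int(nrow(rates), n_reads, replace = TRUE, prob = w)
    pos <- floor(stats::runif(n_reads, rates$start[seg], rates$end[seg]))
    p_fwd <- rates$fwd_rate[seg] / tot[seg]
    strand <- ifelse(stats::runif(n_reads) < p_fwd, "+", "-")
    reads <- data.frame(chrom = chrom, start = pos, end = pos + read_len,
                        name = sprintf("read%06d", seq_len(n_reads)),
                        score = 0L, strand = strand, stringsAsFactors = FALSE)
    list(reads = reads[order(reads$start), , drop = FALSE],
         truth = list(rates = rates, n_reads = n_reads, seed = seed))
  })
}

#' Simulate bisulfite clones of one allele
#'
#' CpG calls are Bernoulli(`p`) per position, no-calls (`N`) injected at
#' `no_call_rate`, and the non-CpG conversion failures are binomial with
#' rate `conversion_failure_rate` over `n_non_cpg` non-CpG cytosines.
#'
#' @param n_clones number of clones.
#' @param n_cpgs CpGs per clone.
#' @param p per-CpG methylation probability of this allele.
#' @param conversion_failure_rate probability a non-CpG cytosine fails
#'   conversion (default 0.01).
#' @param no_call_rate probability a CpG is unreadable (default 0.02).
#' @param n_non_cpg non-CpG cytosines per clone (default 50).
#' @param allele,amplicon metadata labels.
#' @param seed RNG seed.
#' @return list with `clones` (see [bisulfite_clones()]) and `truth`.
#' @export
sim_bisulfite <- function(n_clones, n_cpgs, p, conversion_failure_rate = 0.01,
                          no_call_rate = 0.02, n_non_cpg = 50,
                          allele = "paternal", amplicon = "F4+R9", seed = 1) {
  stopifnot(p >= 0, p <= 1, conversion_failure_rate >= 0,
            conversion_failure_rate <= 1, no_call_rate >= 0, no_call_rate < 1)
  with_sim_seed(seed, {
    calls <- vapply(seq_len(n_clones), function(i) {
      v <- ifelse(stats::runif(n_cpgs) < p, "M", "U")
      v[stats::runif(n_cpgs) < no_call_rate] <- "N"
      paste(v, collapse = "")
    }, "")
    unconv <- stats::rbinom(n_clones, n_non_cpg, conversion_failure_rate)
    clones <- bisulfite_clones(sprintf("clone%03d", seq_len(n_clones)),
                               amplicon, allele, calls,
                               rep(n_non_cpg, n_clones), unconv)
    list(clones = clones,
         truth = list(p = p, conversion_failure_rate = conversion_failure_rate,
                      no_call_rate = no_call_rate, n_cpgs = n_cpgs,
                      n_non_cpg = n_non_cpg, seed = seed))
  })
}

#' Simulate an allele-specific qPCR differentiation series
#'
#' For each condition the maternal allele quantity is `true_ratio` and the
#' paternal quantity 1 on an arbitrary common scale; Ct values are
#' generated under perfect doubling (`Ct = ct0 - log2(quantity)`) with
#' Gaussian Ct noise, then converted back to quantities, so with zero noise
#' the true ratios are recovered exactly.
#'
#' @param conditions data.frame with columns `condition` and `true_ratio`
#'   (positive).
#' @param n_replicates replicates per condition (default 3).
#' @param ct_noise_sd Gaussian noise on Ct values (default 0.1 cycles).
#' @param ct0 baseline Ct of one quantity unit (default 20).
#' @param seed RNG seed.
#' @return list with `quantities` (data.frame `condition`, `replicate`,
#'   `mat_ct`, `pat_ct`, `mat_qty`, `pat_qty`) and `truth`.
#' @export
sim_allelic_series <- function(conditions, n_replicates = 3, ct_noise_sd = 0.1,
                               ct0 = 20, seed = 1) {
  if (any(conditions$true_ratio <= 0)) stop("true ratios must be positive")
  with_sim_seed(seed, {
    rows <- expand.grid(replicate = seq_len(n_replicates),
                        i = seq_len(nrow(conditions)))
    ratio <- conditions$true_ratio[rows$i]
    n <- nrow(rows)
    mat_ct <- ct0 - log2(ratio) + stats::rnorm(n, 0, ct_noise_sd)
    pat_ct <- ct0 + stats::rnorm(n, 0, ct_noise_sd)
    list(quantities = data.frame(condition = conditions$condition[rows$i],
                                 replicate = rows$replicate,
                                 mat_ct = mat_ct, pat_ct = pat_ct,
                                 mat_qty = 2^(-(mat_ct - ct0)),
                                 pat_qty = 2^(-(pat_ct - ct0)),
                                 stringsAsFactors = FALSE),
         truth = list(conditions = conditions, n_replicates = n_replicates,
                      ct_noise_sd = ct_noise_sd, seed = seed))
  })
}

#' Simulate litter genotype counts
#'
#' @param n litter size.
#' @param weights positive Mendelian class weights (default 1:2:1).
#' @param labels class labels.
#' @param seed RNG seed.
#' @return list with `counts` (named integer vector) and `truth`.
#' @export
sim_litter <- function(n, weights = c(1, 2, 1),
                       labels = c("wildtype", "heterozygote", "homozygote"),
                       seed = 1) {
  stopifnot(length(weights) == length(labels), all(weights > 0), n >= 0)
  with_sim_seed(seed, {
    counts <- as.integer(stats::rmultinom(1, n, weights / sum(weights)))
    names(counts) <- labels
    list(counts = counts, truth = list(weights = weights, n = n, seed = seed))
  })
}
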