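#' Bisulfite clone tables
#'
#' A sequenced bisulfite clone is one row: `clone_id`, `amplicon` (the
#' primer-pair label that determines which allele was amplified),
#' `allele` (`maternal`, `paternal` or `unknown`; metadata-driven, no
#' alignment is performed), `cpg_calls` (a string over `M` methylated,
#' `U` unmethylated, `N` no-call), and the conversion-QC counts
#' `non_cpg_total` / `non_cpg_unconverted` (non-CpG cytosines seen and
#' those that failed bisulfite conversion).
#'
#' @param clone_id,amplicon,allele,cpg_calls character vectors.
#' @param non_cpg_total,non_cpg_unconverted integer vectors.
#' @return data.frame with the columns above.
#' @export
bisulfite_clones <- function(clone_id, amplicon, allele, cpg_calls,
                             non_cpg_total, non_cpg_unconverted) {
  if (any(!nzchar(cpg_calls))) stop("cpg_calls must be non-empty")
  if (any(grepl("[^MUN]", cpg_calls)))
    stop("cpg_calls may only contain characters M, U, N")
  if (any(non_cpg_unconverted > non_cpg_total) || any(non_cpg_total < 0))
    stop("invalid conversion counts")
  if (!all(allele %in% c("maternal", "paternal", "unknown")))
    stop("allele must be maternal, paternal or unknown")
  data.frame(clone_id = as.character(clone_id), amplicon = as.character(amplicon),
             allele = as.character(allele), cpg_calls = as.character(cpg_calls),
             non_cpg_total = as.integer(non_cpg_total),
             non_cpg_unconverted = as.integer(non_cpg_unconverted),
             stringsAsFactors = FALSE)
}

#' Read / write bisulfite clone TSV
#'
#' Columns: clone_id, amplicon, allele, cpg_calls, non_cpg_total,
#' non_cpg_unconverted. Comment lines start with `#`.
#'
#' @param path file path.
#' @return clone data.frame (see [bisulfite_clones()]).
#' @export
read_clone_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          colClasses = c("character", "character", "character",
                                         "character", "integer", "integer"))
  bisulfite_clones(df$clone_id, df$amplicon, df$allele, df$cpg_calls,
                   df$non_cpg_total, df$non_cpg_unconverted)
}

#' @rdname read_clone_tsv
#' @param clones clone data.frame.
#' @export
write_clone_tsv <- function(clones, path) {
  utils::write.table(clones, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Bisulfite conversion and call-rate quality control
#'
#' A clone passes QC when its non-CpG conversion rate
#' (`1 - unconverted/total`) reaches `min_conversion` and the fraction of
#' CpG positions actually called (non-`N`) reaches `min_called_fraction`.
#' Clones with no non-CpG cytosines carry no conversion evidence and fail.
#' Every exclusion is recorded with its reason.
#'
#' @param clones clone data.frame (see [bisulfite_clones()]).
#' @param min_conversion minimum conversion rate (default 0.95).
#' @param min_called_fraction minimum fraction of called CpGs (default 0.9).
#' @return the clones with added columns `conversion_rate`, `called_fraction`,
#'   `qc_pass`, `qc_reason` (empty string when passing).
#' @export
conversion_qc <- function(clones, min_conversion = 0.95,
                          min_called_fraction = 0.9) {
  conv <- ifelse(clones$non_cpg_total > 0,
                 1 - clones$non_cpg_unconverted / clones$non_cpg_total, NA_real_)
  n_total <- nchar(clones$cpg_calls)
  n_called <- n_total - vapply(gregexpr("N", clones$cpg_calls, fixed = TRUE),
                               function(m) sum(m > 0), 0L)
  called_frac <- n_called / n_total
  reason <- character(nrow(clones))
  reason[clones$non_cpg_total == 0] <- "no conversion evidence"
  low_conv <- reason == "" & conv < min_conversion
  reason[low_conv] <- sprintf("conversion %.3f < %.2f", conv[low_conv], min_conversion)
  low_call <- reason == "" & called_frac < min_called_fraction
  reason[low_call] <- sprintf("called fraction %.3f < %.2f",
                              called_frac[low_call], min_called_fraction)
  out <- clones
  out$conversion_rate <- conv
  out$called_fraction <- called_frac
  out$qc_pass <- reason == ""
  out$qc_reason <- reason
  out
}

#' Per-clone percent methylation
#'
#' `100 * #M / (#M + #U)`; `N` no-calls are excluded from the denominator.
#' A clone with zero called CpGs (which should have failed QC) is an error.
#'
#' @param cpg_calls character vector of call strings over `M`/`U`/`N`.
#' @return numeric vector of percentages.
#' @export
clone_percent_methylation <- function(cpg_calls) {
  counts <- function(ch) vapply(gregexpr(ch, cpg_calls, fixed = TRUE),
                                function(m) sum(m > 0), 0L)
  m <- counts("M"); u <- counts("U")
  if (any(m + u == 0L))
    stop("clone with zero called CpGs (should have failed QC)")
  100 * m / (m + u)
}

#' Summarise methylation of one allele across passing clones
#'
#' @param clones clone data.frame of QC-passing clones of a single
#'   allele/amplicon (at least one row).
#' @return a `methylation_summary`: list with `n_clones`, `per_clone_pct`,
#'   `mean_pct`, `min_pct`, `max_pct` and `per_cpg_fraction` (fraction of
#'   clones methylated at each CpG position, no-calls excluded per
#'   position; NA at positions never called).
#' @export
summarize_allele <- function(clones) {
  if (nrow(clones) == 0L) stop("no passing clones to summarise")
  pct <- clone_percent_methylation(clones$cpg_calls)
  mat <- strsplit(clones$cpg_calls, "")
  width <- max(lengths(mat))
  per_cpg <- vapply(seq_len(width), function(j) {
    calls <- vapply(mat, function(v) if (j <= length(v)) v[j] else "N", "")
    called <- calls %in% c("M", "U")
    if (!any(called)) return(NA_real_)
    sum(calls == "M") / sum(called)
  }, 0)
  structure(list(n_clones = nrow(clones), per_clone_pct = pct,
                 mean_pct = mean(pct), min_pct = min(pct), max_pct = max(pct),
                 per_cpg_fraction = per_cpg),
            class = "methylation_summary")
}

#' @export
print.methylation_summary <- function(x, ...) {
  cat(sprintf("Methylation summary: %d clones\n", x$n_clones))
  cat(sprintf("  mean %.1f%% (extremes %.1f-%.1f%%)\n",
              x$mean_pct, x$min_pct, x$max_pct))
  invisible(x)
}

#' Methylated-to-unmethylated band intensity ratio
#'
#' Quantifies a methyl-sensitive restriction digest blot: the intensity of
#' the methylation-protected band divided by the unmethylated band.
#'
#' @param methylated_signal,unmethylated_signal non-negative intensities;
#'   the unmethylated signal must be positive.
#' @return the ratio (e.g. 0.75 for a 0.75:1 blot).
#' @export
band_ratio <- function(methylated_signal, unmethylated_signal) {
  if (any(unmethylated_signal <= 0)) stop("unmethylated signal must be > 0")
  if (any(methylated_signal < 0)) stop("methylated signal must be >= 0")
  methylated_signal / unmethylated_signal
}

#' qPCR relative quantity (comparative Ct)
#'
#' `100 * efficiency^(-ddCt)` with
#' `ddCt = (ct_target - ct_normalizer) - (ct_target_cal - ct_normalizer_cal)`,
#' i.e. the target normalised to a housekeeping assay and expressed as a
#' percentage of the calibrator condition.
#'
#' @param ct_target,ct_normalizer sample Ct values.
#' @param ct_target_cal,ct_normalizer_cal calibrator Ct values.
#' @param efficiency amplification efficiency per cycle, in (1, 2]
#'   (default 2, perfect doubling).
#' @return percentage of the calibrator.
#' @export
relative_quantity <- function(ct_target, ct_normalizer, ct_target_cal,
                              ct_normalizer_cal, efficiency = 2.0) {
  if (any(efficiency <= 1) || any(efficiency > 2))
    stop("efficiency must be in (1, 2]")
  ddct <- (ct_target - ct_normalizer) - (ct_target_cal - ct_normalizer_cal)
  100 * efficiency^(-ddct)
}

#' Normalised maternal-to-paternal expression ratio
#'
#' The operational measure of imprinting: the maternal/paternal quantity
#' ratio divided by the ratio of a biallelic reference condition (which is
#' therefore 1 exactly).
#'
#' @param mat_qty,pat_qty positive expression quantities on a common scale.
#' @param reference_ratio the raw mat:pat ratio of the reference condition
#'   (default 1).
#' @return normalised mat:pat ratio.
#' @export
allelic_ratio <- function(mat_qty, pat_qty, reference_ratio = 1) {
  if (any(mat_qty <= 0) || any(pat_qty <= 0) || any(reference_ratio <= 0))
    stop("quantities and reference ratio must be positive")
  (mat_qty / pat_qty) / reference_ratio
}

#' Unpaired two-sample t-test with significance stars
#'
#' Two-sided Student test (equal variances) by default, Welch optional.
#' Groups in which both samples have zero variance are handled as t = 0,
#' p = 1 with a warning instead of an error. Stars follow the conventional
#' mapping: `***` p < 0.001, `**` p < 0.01, `*` p < 0.05, `ns` otherwise.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @param equal_variance use the pooled-variance Student test (default
#'   TRUE); FALSE gives Welch.
#' @return list with `t`, `df`, `p`, `stars`.
#' @export
ttest_unpaired <- function(group_a, group_b, equal_variance = TRUE) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each group needs at least 2 observations")
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0) {
    warning("both groups have zero variance; reporting t = 0, p = 1")
    res <- list(t = 0, df = length(group_a) + length(group_b) - 2, p = 1)
  } else {
    tt <- stats::t.test(group_a, group_b, var.equal = equal_variance)
    res <- list(t = unname(tt$statistic), df = unname(tt$parameter),
                p = tt$p.value)
  }
  res$stars <- if (res$p < 0.001) "***" else if (res$p < 0.01) "**"
               else if (res$p < 0.05) "*" else "ns"
  res
}

#' Goodness-of-fit test of genotype class counts
#'
#' Pearson chi-square test of observed litter genotype counts against
#' expected Mendelian weights (e.g. 1:2:1 for a heterozygote intercross).
#'
#' @param counts non-negative integer counts per genotype class.
#' @param expected_weights positive weights (default `c(1, 2, 1)`).
#' @return list with `chi2`, `df`, `p`, `total`, `expected`.
#' @export
genotype_ratio_test <- function(counts, expected_weights = c(1, 2, 1)) {
  if (length(counts) != length(expected_weights))
    stop("counts and expected_weights must have equal length")
  if (any(expected_weights <= 0)) stop("expected weights must be positive")
  if (sum(counts) == 0) stop("total count must be positive")
  p <- expected_weights / sum(expected_weights)
  ct <- suppressWarnings(stats::chisq.test(counts, p = p))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, total = sum(counts), expected = sum(counts) * p)
}
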