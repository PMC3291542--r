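# Independent brute-force oracles used to cross-check the fast implementations.

# Classify every (gene, CGI) pair directly: no sorting, no findInterval.
brute_force_associate <- function(tss, cgis, orient_by_strand = TRUE) {
  out <- data.frame(gene_id = tss$gene_id,
                    relation = rep("unassociated", nrow(tss)),
                    bin_index = rep(NA_integer_, nrow(tss)),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(tss))) {
    hits <- c(); mids <- c(); rels <- c(); starts <- c()
    for (j in seq_len(nrow(cgis))) {
      if (cgis$chrom[j] != tss$chrom[i]) next
      L <- cgis$end[j] - cgis$start[j]
      ws <- cgis$start[j] - floor(L / 2)
      we <- cgis$end[j] + ceiling(L / 2)
      pos <- tss$pos[i]
      if (pos >= max(ws, 0) && pos < we) {
        rel <- if (orient_by_strand && tss$strand[i] == "-")
          (we - 1 - pos) / (we - ws) else (pos - ws) / (we - ws)
        hits <- c(hits, j)
        mids <- c(mids, (cgis$start[j] + cgis$end[j]) / 2)
        rels <- c(rels, rel)
        starts <- c(starts, cgis$start[j])
      }
    }
    if (length(hits) == 0) next
    d <- abs(tss$pos[i] - mids)
    k <- order(d, starts)[1]
    rel <- rels[k]
    out$relation[i] <- if (rel >= 0.25 && rel < 0.75) "inside"
      else if (rel < 0.25) "upstream_flank" else "downstream_flank"
    out$bin_index[i] <- min(floor(100 * rel), 99)
  }
  out
}

# Pearson goodness of fit evaluated directly from the definition.
brute_force_chi2 <- function(obs, weights) {
  e <- sum(obs) * weights / sum(weights)
  sum((obs - e)^2 / e)
}

# Random but valid interval table for round-trip properties.
random_intervals <- function(n, seed) {
  set.seed(seed)
  chrom <- sample(paste0("chr", 1:5), n, replace = TRUE)
  start <- sample.int(1e6, n)
  width <- sample.int(5000, n)
  genome_intervals(chrom, start, start + width,
                   strand = sample(c("+", "-", "*"), n, replace = TRUE),
                   name = sprintf("f%05d", seq_len(n)))
}
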