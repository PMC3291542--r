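test_that("extended_window adds proportional 50% flanks and clips at 0", {
  w <- extended_window(genome_intervals("chr1", 1000, 2000))
  expect_equal(c(w$win_start, w$win_end), c(500, 2500))
  expect_false(w$clipped)

  w <- extended_window(genome_intervals("chr1", 0, 1000))
  expect_equal(c(w$win_start, w$win_end), c(0, 1500))
  expect_true(w$clipped)

  # odd length splits floor/ceil and conserves total window length 2L
  w <- extended_window(genome_intervals("chr1", 1000, 2001))
  expect_equal(c(w$win_start, w$win_end), c(500, 2502))
  expect_equal(w$win_end - w$win_start, 2 * 1001)
})

test_that("associate_tss classifies positions in transcript orientation", {
  cgis <- genome_intervals("chr1", 1000, 2000)

  a <- associate_tss(tss_set("g1", "chr1", 1500, "+"), cgis)
  expect_equal(a$relation, "inside")
  expect_equal(a$relative_coord, 0.5)
  expect_equal(a$bin_index, 50)

  a <- associate_tss(tss_set("g1", "chr1", 600, "+"), cgis)
  expect_equal(a$relation, "upstream_flank")
  expect_equal(a$relative_coord, 0.05)
  expect_equal(a$bin_index, 5)

  # minus strand mirrors the window: same genomic point is now downstream
  a <- associate_tss(tss_set("g1", "chr1", 600, "-"), cgis)
  expect_equal(a$relation, "downstream_flank")
  expect_equal(a$bin_index, 94)
  expect_equal(a$relative_coord, (2499 - 600) / 2000)

  # outside the extended window
  a <- associate_tss(tss_set("g1", "chr1", 400, "+"), cgis)
  expect_equal(a$relation, "unassociated")
  expect_true(is.na(a$bin_index))
})

test_that("overlapping windows resolve to the nearest island midpoint", {
  cgis <- genome_intervals(c("chr1", "chr1"), c(1000, 1800), c(1600, 2400))
  # TSS at 1650: inside both extended windows [700,1900) and [1500,2700);
  # midpoints 1300 and 2100 -> nearer to 1300? |1650-1300|=350, |1650-2100|=450
  a <- associate_tss(tss_set("g1", "chr1", 1650, "+"), cgis)
  expect_equal(a$cgi_index, 1L)
  # equidistant tie breaks to the lower start coordinate
  a <- associate_tss(tss_set("g1", "chr1", 1700, "+"), cgis)
  expect_equal(a$cgi_index, 1L)
})

test_that("build_profile computes counts and fractions over the right denominators", {
  # constructed by hand: 6 inside / 2 upstream / 1 downstream / 1 unassociated
  cgis <- genome_intervals(rep("chr1", 10), seq(0, 9) * 100000 + 10000,
                           seq(0, 9) * 100000 + 11000)
  w <- extended_window(cgis)
  pos <- c(w$win_start[1:6] + 1000,   # relative 0.5 -> inside
           w$win_start[7:8] + 10,     # upstream flank
           w$win_start[9] + 1900,     # relative 0.95 -> downstream flank
           w$win_end[10] + 50000)     # far away -> unassociated
  genes <- tss_set(sprintf("g%d", 1:10), rep("chr1", 10), pos, rep("+", 10))
  prof <- build_profile(genes, cgis)
  expect_s3_class(prof, "metagene_profile")
  expect_length(prof$bins, 100)
  expect_equal(sum(prof$bins), 9)
  expect_equal(prof$n_associated, 9)
  expect_equal(unname(prof$fractions["associated"]), 90)
  expect_equal(unname(prof$fractions["inside"]), 100 * 6 / 9)
  expect_equal(unname(prof$fractions["upstream"]), 100 * 2 / 9)
  expect_equal(unname(prof$fractions["downstream"]), 100 * 1 / 9)
})

test_that("degenerate gene sets are reported as missing, not zero", {
  cgis <- genome_intervals("chr1", 1000, 2000)
  empty <- tss_set(character(), character(), numeric(), character())
  prof <- build_profile(empty, cgis)
  expect_equal(sum(prof$bins), 0)
  expect_true(all(is.na(prof$fractions)))

  # all genes unassociated: associated fraction 0, class fractions undefined
  genes <- tss_set(c("g1", "g2"), "chr1", c(10, 100000), c("+", "-"))
  prof <- build_profile(genes, cgis)
  expect_equal(sum(prof$bins), 0)
  expect_equal(unname(prof$fractions["associated"]), 0)
  expect_true(is.na(prof$fractions["inside"]))
})

test_that("counts are conserved: bins + unassociated = total genes", {
  for (seed in 1:3) {
    sim <- sim_annotation(300, seed = seed)
    prof <- build_profile(sim$genes, sim$cgis)
    expect_length(prof$bins, 100)
    expect_equal(sum(prof$bins) +
                   sum(prof$associations$relation == "unassociated"),
                 nrow(sim$genes))
  }
})

test_that("profiles are equivariant under coordinate mirror plus strand flip", {
  # Even island lengths: the floor/ceil flank split of odd lengths puts the
  # extra base downstream in genomic orientation, so exact mirror symmetry
  # is a property of the even-length geometry.
  set.seed(5)
  n <- 200
  L <- 2 * sample(100:1000, n, replace = TRUE)
  ws <- 20000 * seq_len(n)
  cgis <- genome_intervals(rep("chrS", n), ws, ws + L)
  pos <- ws - L + sample.int(3 * max(L), n, replace = TRUE) %% (3 * L)
  pos <- pmax(pos, 0)
  genes <- tss_set(sprintf("g%d", seq_len(n)), "chrS", pos,
                   sample(c("+", "-"), n, replace = TRUE))
  P <- 1e9  # mirror pivot, large enough to keep coordinates positive
  m_cgis <- genome_intervals(cgis$chrom, P - cgis$end, P - cgis$start)
  m_genes <- tss_set(genes$gene_id, genes$chrom, P - 1 - genes$pos,
                     ifelse(genes$strand == "+", "-", "+"))
  a <- build_profile(genes, cgis)
  b <- build_profile(m_genes, m_cgis)
  expect_identical(a$bins, b$bins)
  expect_identical(a$fractions, b$fractions)
})

test_that("fast association matches the brute-force pairwise classifier", {
  set.seed(99)
  for (rep in 1:3) {
    n_cgi <- 12
    starts <- sort(sample.int(5e5, n_cgi))
    cgis <- genome_intervals(sample(c("chrA", "chrB"), n_cgi, TRUE),
                             starts, starts + sample(200:3000, n_cgi, TRUE))
    genes <- tss_set(sprintf("g%d", 1:50),
                     sample(c("chrA", "chrB", "chrC"), 50, TRUE),
                     sample.int(6e5, 50), sample(c("+", "-"), 50, TRUE))
    fast <- associate_tss(genes, cgis)
    slow <- brute_force_associate(genes, cgis)
    expect_equal(fast$relation, slow$relation)
    expect_equal(fast$bin_index, slow$bin_index)
  }
})
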