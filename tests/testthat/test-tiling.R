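test_that("tukey biweight equals the centre on clean data and resists outliers", {
  expect_equal(tukey_biweight_location(c(5, 5, 5, 5)), 5)
  expect_equal(tukey_biweight_location(1:5), 3)
  # frozen from an independent evaluation of the one-step definition
  expect_equal(tukey_biweight_location(c(1, 2, 3, 4, 100)), 2.602340288333645,
               tolerance = 1e-12)
  est <- tukey_biweight_location(c(1, 2, 3, 4, 100))
  expect_gt(est, 2); expect_lt(est, 4)
  expect_lt(est, mean(c(1, 2, 3, 4, 100)))
  # bounded response: the outlier's size is immaterial once rejected
  expect_equal(tukey_biweight_location(c(1, 2, 3, 4, 1e9)),
               tukey_biweight_location(c(1, 2, 3, 4, 100)))
  expect_error(tukey_biweight_location(numeric(0)), "empty")
})

test_that("relative intensities average to 1 over the region", {
  probes <- data.frame(chrom = "c", start = 0:99 * 100, end = 0:99 * 100 + 50,
                       cdna = 7, gdna = 7)
  expect_equal(relative_intensity(probes), rep(1, 100))

  # two-segment track with a 2:1 true ratio and no noise
  probes$cdna <- rep(c(2, 1), each = 50)
  v <- relative_intensity(probes)
  expect_equal(unique(v[1:50]), 4 / 3)
  expect_equal(unique(v[51:100]), 2 / 3)

  set.seed(3)
  probes$cdna <- rexp(100) + 0.1
  probes$gdna <- rexp(100) + 0.5
  expect_equal(mean(relative_intensity(probes)), 1, tolerance = 1e-9)

  probes$cdna <- 0
  expect_warning(v <- relative_intensity(probes), "all cDNA")
  expect_equal(v, rep(0, 100))

  probes$gdna[1] <- 0
  expect_error(relative_intensity(probes), "genomic signal")
})

test_that("masks remove exactly the overlapping probes", {
  probes <- data.frame(chrom = "c", start = 0:999 * 100, end = 0:999 * 100 + 50,
                       cdna = 1, gdna = 1)
  expect_identical(apply_masks(probes, genome_intervals("other", 0, 1e6)), probes)
  # mask spanning a known 10-probe run
  mask <- genome_intervals("c", 100 * 100, 100 * 110)
  expect_message(kept <- apply_masks(probes, mask), "masked out 10")
  expect_equal(nrow(kept), 990)
  expect_false(any(kept$start >= 100 * 100 & kept$start < 100 * 110))
  expect_warning(apply_masks(probes, genome_intervals("c", 0, 1e6)), "all probes")
})

test_that("smoothing groups 9-tile windows into blocks of 20", {
  pos <- seq(0, by = 100, length.out = 28)
  prof <- smooth_profile(pos, rep(2.5, 28))
  expect_s3_class(prof, "ri_profile")
  expect_equal(nrow(prof), 1)          # 28 probes -> exactly 20 windows
  expect_equal(prof$n_windows, 20)
  expect_false(prof$partial)
  expect_equal(prof$mean, 2.5)
  expect_equal(prof$sd, 0)

  # a trailing short block is emitted and flagged, never averaged as full
  pos <- seq(0, by = 100, length.out = 40)
  prof <- smooth_profile(pos, rep(1, 40))
  expect_equal(nrow(prof), 2)
  expect_equal(prof$n_windows, c(20, 12))
  expect_equal(prof$partial, c(FALSE, TRUE))

  expect_error(smooth_profile(1:8 * 100, rep(1, 8)), "at least 9")
  expect_error(smooth_profile(rep(1, 20), rep(1, 20)), "strictly increasing")
})

test_that("points bracketing a sharp drop carry larger sd than flat regions", {
  pos <- seq(0, by = 100, length.out = 80)
  vals <- rep(c(2, 0.1), each = 40)
  prof <- smooth_profile(pos, vals)
  # block 2 (probes ~28-55) straddles the step at probe 40
  expect_gt(prof$sd[2], 10 * prof$sd[1])
})

test_that("segment_region tiles the oriented locus into three adjacent parts", {
  seg <- segment_region(-62000, 28000, 118000)
  expect_equal(seg$igf2r_specific$start, -62000)
  expect_equal(seg$igf2r_specific$end, seg$overlap$start)
  expect_equal(seg$overlap$end, seg$transcript_specific$start)
  expect_equal(seg$transcript_specific$end, 118000)
  total <- sum(vapply(seg, function(s) s$end - s$start, 0))
  expect_equal(total, 180000)

  expect_s3_class(segment_region(-1000, 1000, 2000), "region_segmentation")
  expect_error(segment_region(-1000, 2000, 2000), "strictly increasing")
  expect_error(segment_region(1000, 2000, 3000), "strictly increasing")
})

test_that("call_extent is silent on identical profiles and strict about grids", {
  sim <- sim_tiling(noise_sd = 0, seed = 1)
  v <- relative_intensity(sim$probes)
  prof <- smooth_profile(sim$probes$start + 25, v)
  bg <- estimate_background(prof, 120000, 130000)
  call <- call_extent(prof, prof, bg,
                      segment = segment_region(-62000, 28000, 118000)$transcript_specific)
  expect_true(is.na(call$reduction_start))
  expect_true(is.na(call$absence_start))
  expect_equal(call$criterion_params, list(delta = 0.25, k = 3, z = 2))

  shifted <- prof
  shifted$position <- shifted$position + 1
  expect_error(call_extent(shifted, prof, bg), "share point positions")
})

test_that("truncation boundaries are recovered and move with the truth", {
  seg <- segment_region(-62000, 28000, 118000)
  wt <- sim_tiling(noise_sd = 0.1, seed = 42)
  wt_prof <- smooth_profile(wt$probes$start + 25, relative_intensity(wt$probes))
  absence <- vapply(c(80000, 90000, 100000), function(tr) {
    mut <- sim_tiling(decline_start = 68000, truncation = tr, noise_sd = 0.1,
                      seed = 42)
    prof <- smooth_profile(mut$probes$start + 25, relative_intensity(mut$probes))
    bg <- estimate_background(prof, 120000, 130000)
    call_extent(prof, wt_prof, bg, segment = seg$transcript_specific,
                calibration = seg$igf2r_specific)$absence_start
  }, 0)
  expect_true(all(abs(absence - c(80000, 90000, 100000)) <= 2000))
  # monotone in the truth truncation point
  expect_true(all(diff(absence) > 0))
})

test_that("strand log ratios are antisymmetric and respect masks", {
  region <- data.frame(chrom = "c", start = 0, end = 32000)
  set.seed(8)
  reads <- data.frame(chrom = "c", start = sample.int(32000, 4000) - 1,
                      strand = sample(c("+", "-"), 4000, TRUE),
                      stringsAsFactors = FALSE)
  r1 <- strand_log_ratio(reads, region)
  expect_equal(nrow(r1), 10)
  expect_equal(r1$end - r1$start, rep(3200, 10))

  flipped <- reads
  flipped$strand <- ifelse(reads$strand == "+", "-", "+")
  r2 <- strand_log_ratio(flipped, region)
  expect_equal(r2$log2_ratio, -r1$log2_ratio)

  masks <- genome_intervals("c", 6400, 10000)
  rm <- strand_log_ratio(reads, region, masks = masks)
  expect_true(all(rm$masked[3:4]))
  expect_true(all(is.na(rm$log2_ratio[rm$masked])))
  expect_false(any(rm$masked[-(3:4)]))

  expect_error(strand_log_ratio(reads, region, window_size = 0), "positive")
})

test_that("strand ratio pseudocount arithmetic matches hand computation", {
  reads <- data.frame(chrom = "c",
                      start = c(rep(10, 8), rep(20, 2)),
                      strand = c(rep("+", 8), rep("-", 2)),
                      stringsAsFactors = FALSE)
  region <- data.frame(chrom = "c", start = 0, end = 3200)
  expect_equal(strand_log_ratio(reads, region, alpha = 0)$log2_ratio, 2)
  expect_equal(strand_log_ratio(reads, region, alpha = 1)$log2_ratio,
               log2(9 / 3))
  # equal counts give ratio 0; empty windows carry no ratio
  region2 <- data.frame(chrom = "c", start = 0, end = 6400)
  r <- strand_log_ratio(reads, region2)
  expect_equal(r$log2_ratio[1], log2(9 / 3))
  expect_true(is.na(r$log2_ratio[2]))  # no reads on either strand
  expect_true(r$masked[2])
  even <- data.frame(chrom = "c", start = c(1, 2, 3, 4),
                     strand = c("+", "+", "-", "-"), stringsAsFactors = FALSE)
  expect_equal(strand_log_ratio(even, region)$log2_ratio, 0)
})
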