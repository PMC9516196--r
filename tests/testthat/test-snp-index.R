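test_that("quality thresholds are inclusive and match a brute-force predicate", {
  rec <- variant_records("chr01", c(100, 200, 300), "G", "A",
                         alt_depth = c(5, 5, 5), total_depth = 10,
                         mapping_quality = c(30, 29, 60),
                         base_quality = c(20, 40, 19))
  kept <- quality_filter(rec)
  expect_equal(kept$pos, 100)  # MQ 29 and BQ 19 rows removed, boundary kept

  many <- random_records(1000, seed = 1)
  cfg <- filter_config()
  keep <- vapply(seq_len(nrow(many)), function(i) {
    many$mapping_quality[i] >= cfg$min_mapping_quality &&
      many$base_quality[i] >= cfg$min_base_quality
  }, logical(1))
  expect_equal(quality_filter(many, cfg), many[keep, ],
               ignore_attr = TRUE)
})

test_that("shared-SNP exclusion subtracts on the full allele key", {
  v1 <- variant_records("chr01", 100, "G", "A", 10, 20)
  v2 <- variant_records("chr01", 200, "C", "T", 10, 20)
  target <- rbind(v1, v2)
  expect_equal(exclude_shared(target, wild_type = v2)$pos, 100)
  # same position, different alt allele: not removed
  v2b <- variant_records("chr01", 200, "C", "G", 10, 20)
  expect_equal(nrow(exclude_shared(target, wild_type = v2b)), 2)
  # presence needs >= 2 alt reads in the comparison set
  weak <- variant_records("chr01", 200, "C", "T", 1, 20)
  expect_equal(nrow(exclude_shared(target, wild_type = weak)), 2)
  # conflicting reference alleles at one coordinate are an integrity error
  bad <- variant_records("chr01", 200, "A", "T", 10, 20)
  expect_error(exclude_shared(target, wild_type = bad),
               class = "mutmapr_integrity_error")
})

test_that("the SNP index is the alt-read fraction, with a depth floor on the track", {
  rec <- variant_records("chr01", c(1, 2, 3), "G", "A",
                         alt_depth = c(20, 10, 7), total_depth = 20)
  expect_equal(compute_snp_index(rec), c(1, 0.5, 0.35))
  shallow <- variant_records("chr01", 4, "G", "A", 2, 4)
  track <- snp_index_track(rbind(rec, shallow))
  expect_equal(nrow(track), 3)
  expect_equal(attr(track, "n_low_depth"), 1)
  expect_true(all(track$snp_index >= 0 & track$snp_index <= 1))
})

test_that("window means equal brute-force recomputation", {
  rec <- variant_records("chr01", c(10, 500, 900), "G", "A",
                         alt_depth = c(20, 16, 18), total_depth = 20)
  scan <- scan_genome(rec, window_size = 1000, step = 1000,
                      min_sites_per_window = 1)
  expect_equal(scan$windows$mean_index[1], mean(c(1, 0.8, 0.9)))

  const <- variant_records("chr01", seq(1, 9901, by = 100), "G", "A",
                           alt_depth = 10, total_depth = 20)
  sc <- scan_genome(const, window_size = 2000, step = 500,
                    min_sites_per_window = 1)
  expect_true(all(sc$windows$mean_index == 0.5))

  rnd <- random_records(300, seed = 2)
  rnd$pos <- sort(sample.int(5e4, 300))
  sc <- scan_genome(rnd, window_size = 7000, step = 1300,
                    min_sites_per_window = 2)
  tr <- sc$sites
  for (i in sample(nrow(sc$windows), 25)) {
    w <- sc$windows[i, ]
    inw <- tr$chrom == w$chrom & tr$pos >= w$start & tr$pos < w$start + 7000
    expected <- if (sum(inw) >= 2) mean(tr$snp_index[inw]) else NA_real_
    expect_equal(w$mean_index, expected)
  }
  expect_error(scan_genome(rnd, window_size = 0),
               class = "mutmapr_parameter_error")
})

test_that("peak calling returns nothing at index 0.5 and is deterministic", {
  flat <- variant_records("chr01", seq(1e4, 2e6, by = 1e4), "G", "A",
                          alt_depth = 10, total_depth = 20)
  scan <- scan_genome(flat)
  expect_equal(nrow(call_peak_regions(scan)), 0)
  expect_error(call_peak_regions(data.frame()), class = "mutmapr_parameter_error")

  g <- default_genome()
  line <- simulate_mutagenesis(
    g, 2000, list(chrom = "chr07", pos = 1600000, ref = "G", alt = "A"),
    seed = 5)
  pool <- simulate_f2_pool(line, g, f2_pool_spec(40, depth = 25, seed = 6))
  r1 <- map_mutant_pool(pool)
  r2 <- map_mutant_pool(pool)
  expect_identical(r1$regions, r2$regions)
  expect_equal(r1$regions$chrom[1], "chr07")
  expect_true(r1$regions$start[1] <= 1600000 &&
                r1$regions$end[1] >= 1600000)
})

test_that("cross-exclusion removes fixed parental SNPs that would otherwise be false candidates", {
  g <- default_genome()
  causal <- list(chrom = "chr07", pos = 1600000, ref = "G", alt = "A")
  line <- simulate_mutagenesis(g, 200, causal, seed = 7)
  shared <- data.frame(chrom = rep(c("chr02", "chr05"), each = 10),
                       pos = rep(seq(2e6, 20e6, by = 2e6), 2),
                       ref = "T", alt = "C")
  pool <- simulate_f2_pool(line, g, f2_pool_spec(30, depth = 25, seed = 8),
                           shared_variants = shared)
  wt <- simulate_wildtype_pool(shared, depth = 25, seed = 9)
  with_excl <- map_mutant_pool(pool, wild_type = wt)
  without_excl <- map_mutant_pool(pool)
  near_fixed <- function(res) {
    tr <- res$scan$sites
    sum(tr$snp_index >= 0.9 & tr$chrom != "chr07")
  }
  # dropping the exclusion step strictly increases false candidates
  expect_gt(near_fixed(without_excl), near_fixed(with_excl))
  # the causal SNP itself always survives exclusion
  keys <- with(with_excl$records, paste(chrom, pos, ref, alt))
  expect_true("chr07 1600000 G A" %in% keys)
})

test_that("map-rate estimation from index decay is plausible on one pool", {
  g <- default_genome()
  line <- simulate_mutagenesis(
    g, 2000, list(chrom = "chr07", pos = 1600000, ref = "G", alt = "A"),
    seed = 11)
  pool <- simulate_f2_pool(line, g, f2_pool_spec(76, depth = 100, seed = 12))
  est <- estimate_map_rate(snp_index_track(pool), "chr07", 1600000)
  expect_gt(est$n_sites, 10)
  expect_gt(est$cm_per_mb, 2)
  expect_lt(est$cm_per_mb, 6)
})
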