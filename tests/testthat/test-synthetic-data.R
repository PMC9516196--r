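causal7 <- list(chrom = "chr07", pos = 1600000, ref = "G", alt = "A")

test_that("mutagenesis plants the causal SNP and draws background from the spectrum", {
  g <- default_genome()

  only_causal <- simulate_mutagenesis(g, 0, causal7, seed = 1)
  expect_equal(nrow(only_causal$background), 0)
  expect_equal(nrow(line_variants(only_causal)), 1)
  expect_equal(only_causal$causal$ref, "G")
  expect_equal(only_causal$causal$alt, "A")

  line <- simulate_mutagenesis(g, 2000, causal7, seed = 2)
  expect_equal(nrow(line$background), 2000)
  expect_false(any(duplicated(paste(line$background$chrom,
                                    line$background$pos))))
  # substitution-class frequencies within 3 Monte-Carlo SE of the spectrum
  cls <- mapply(mutmapr:::substitution_class,
                line$background$ref, line$background$alt)
  p_gc_at <- mean(cls == "GC>AT")
  se <- sqrt(0.85 * 0.15 / 2000)
  expect_lt(abs(p_gc_at - 0.85), 3 * se)
  chisq <- suppressWarnings(
    chisq.test(table(factor(cls, levels = names(default_spectrum()))),
               p = default_spectrum()))
  expect_gt(chisq$p.value, 1e-3)
})

test_that("mutagenesis is deterministic under a seed and validates bounds", {
  g <- default_genome()
  a <- simulate_mutagenesis(g, 200, causal7, seed = 7)
  b <- simulate_mutagenesis(g, 200, causal7, seed = 7)
  expect_identical(a, b)
  c <- simulate_mutagenesis(g, 200, causal7, seed = 8)
  expect_false(identical(a$background, c$background))

  expect_error(
    simulate_mutagenesis(g, 0, list(chrom = "chr07", pos = 9e9,
                                    ref = "G", alt = "A")),
    class = "mutmapr_parameter_error")
  expect_error(
    simulate_mutagenesis(g, 0, list(chrom = "chrXX", pos = 5,
                                    ref = "G", alt = "A")),
    class = "mutmapr_parameter_error")
})

test_that("mutagenesis respects an attached reference sequence", {
  g <- genome_spec(data.frame(name = "chr1", length = 2000), cm_per_mb = 4)
  g <- random_genome_sequence(g, seed = 3)
  base_at_50 <- as.character(Biostrings::subseq(g$sequence[["chr1"]], 50, 50))
  wrong <- setdiff(c("A", "C", "G", "T"), base_at_50)[1]
  expect_error(
    simulate_mutagenesis(g, 0, list(chrom = "chr1", pos = 50,
                                    ref = wrong, alt = base_at_50)),
    class = "mutmapr_integrity_error")
  line <- simulate_mutagenesis(
    g, 50, list(chrom = "chr1", pos = 50, ref = base_at_50,
                alt = setdiff(c("A", "C", "G", "T"), base_at_50)[1]),
    seed = 4)
  refs <- vapply(seq_len(50), function(i)
    as.character(Biostrings::subseq(g$sequence[["chr1"]],
                                    line$background$pos[i],
                                    line$background$pos[i])),
    character(1))
  expect_equal(line$background$ref, refs)
})

test_that("selection fixes the causal allele and leaves unlinked loci at 1/2", {
  g <- default_genome()
  line <- simulate_mutagenesis(g, 300, causal7, seed = 10)
  pool <- simulate_f2_pool(line, g, f2_pool_spec(40, depth = 30, seed = 11))
  expect_equal(pool$true_freq[pool$source == "causal"], 1)
  expect_true(all(pool$true_freq >= 0 & pool$true_freq <= 1))
  # mean over unlinked (off-chromosome) loci within 3 SE of 0.5; the SE is
  # taken over per-chromosome means because linked sites are correlated
  unl <- pool[pool$chrom != "chr07", ]
  chrom_means <- tapply(unl$true_freq, unl$chrom, mean)
  se <- sd(chrom_means) / sqrt(length(chrom_means))
  expect_lt(abs(mean(chrom_means) - 0.5), 3 * se)
})

test_that("a locus at recombination fraction r has expected index 1 - r", {
  g <- default_genome()
  # place one linked marker at genetic distance d with Haldane r = 0.1:
  # d = -log(1 - 2r)/2 Morgans = 11.157 cM -> 2.789 Mb at 4 cM/Mb
  d_bp <- round(-log(0.8) / 2 * 100 / 4 * 1e6)
  line <- structure(list(
    line_id = "linked", causal = as.data.frame(causal7,
                                               stringsAsFactors = FALSE),
    background = data.frame(chrom = "chr07", pos = causal7$pos + d_bp,
                            ref = "C", alt = "T"),
    spectrum = default_spectrum()), class = "mutant_line")
  freqs <- vapply(1:40, function(i) {
    pool <- simulate_f2_pool(line, g,
                             f2_pool_spec(20, depth = 50, seed = 100 + i))
    pool$true_freq[pool$source == "background"]
  }, numeric(1))
  se <- sd(freqs) / sqrt(length(freqs))
  expect_lt(abs(mean(freqs) - 0.9), 3 * se)
})

test_that("pool simulation is deterministic under a seed", {
  g <- default_genome()
  line <- simulate_mutagenesis(g, 100, causal7, seed = 20)
  spec <- f2_pool_spec(10, depth = 20, seed = 21)
  expect_identical(simulate_f2_pool(line, g, spec),
                   simulate_f2_pool(line, g, spec))
})

test_that("shared parental variants are fixed in the pool and in the wild type", {
  g <- default_genome()
  line <- simulate_mutagenesis(g, 10, causal7, seed = 30)
  shared <- data.frame(chrom = "chr01", pos = c(1e6, 2e6),
                       ref = "T", alt = "G")
  pool <- simulate_f2_pool(line, g, f2_pool_spec(15, depth = 20, seed = 31),
                           shared_variants = shared)
  expect_equal(pool$true_freq[pool$source == "shared"], c(1, 1))
  wt <- simulate_wildtype_pool(shared, depth = 20, seed = 32)
  expect_equal(nrow(wt), 2)
  expect_true(all(wt$alt_depth >= 0.5 * wt$total_depth))
  expect_equal(nrow(simulate_wildtype_pool(NULL)), 0)
})

test_that("DEG tables realize planted overlap and concordance exactly", {
  profiles <- pair_overlap_profiles(
    c("mut_b", "mut_a"), sizes = c(1214, 1345), intersection = 757,
    concordance = 729 / 757, down_down_frac = 666 / 729,
    down = c(866, 1128))
  spec <- deg_sim_spec(20000, profiles, seed = 40)
  tabs <- simulate_deg_tables(spec)
  degs <- lapply(tabs, filter_degs)
  ov <- overlap_summary(degs)
  expect_equal(ov$pairs$intersection, 757)
  expect_equal(ov$pairs$same_direction, 729)
  expect_equal(ov$pairs$down_down, 666)
  expect_equal(ov$sets$n_deg, c(1214, 1345))
  # construction: filter recovers the planted direction labels exactly
  for (nm in names(tabs)) {
    planted <- tabs[[nm]]$gene_id[tabs[[nm]]$true_direction != "none"]
    expect_setequal(degs[[nm]]$gene_id, planted)
  }
  # deterministic under seed
  expect_identical(tabs, simulate_deg_tables(spec))
})

test_that("empty planting yields empty DEG sets; infeasible planting errors", {
  spec <- deg_sim_spec(100, data.frame(a = character(0), b = character(0),
                                       count = integer(0)), seed = 41)
  tabs <- simulate_deg_tables(spec)
  expect_equal(nrow(filter_degs(tabs$a)), 0)
  expect_error(
    pair_overlap_profiles(c("a", "b"), sizes = c(10, 20), intersection = 15),
    class = "mutmapr_constraint_error")
  expect_error(
    deg_sim_spec(10, data.frame(a = rep("down", 2), count = c(8, 8))),
    class = "mutmapr_constraint_error")
})

test_that("simulated annotations honour sizes, planting and determinism", {
  universe <- sprintf("g%04d", 1:500)
  deg <- universe[1:50]
  spec <- annotation_sim_spec(
    10, c(5, 20),
    planted = data.frame(term = "hot", size = 20, fold = 4), seed = 50)
  ann <- simulate_annotations(spec, universe, deg_like = deg)
  expect_length(ann, 10)
  # realized overlap is the rounded expectation: 4 * 20 * 50/500 = 8
  expect_equal(length(intersect(ann$hot, deg)), 8)
  expect_identical(ann, simulate_annotations(spec, universe,
                                             deg_like = deg))
  expect_error(
    simulate_annotations(annotation_sim_spec(2, c(5, 600)), universe),
    class = "mutmapr_constraint_error")
  # a term covering the whole universe is degenerate for Fisher
  whole <- fisher_term_test(deg, universe, universe)
  expect_equal(whole$fisher_p, 1)
})
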