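#!/usr/bin/env Rscript
# Simulate the raw material of the mapping experiment: two independent
# mutagenized lines (each one recessive causal SNP on chromosome 7 plus
# ~2,000 sodium-azide-style background SNPs), crossed to their progenitor
# and pooled as phenotype-selected F2s -- 76 mutant individuals for line
# "s_small" and 18 for line "s_large", sequenced at ~20x. Both pools also
# carry ~300 cultivar-vs-reference variants fixed in every individual,
# which is what the wild-type exclusion step exists to remove.
# Writes one VCF per pool (with hidden simulation truth in INFO).

suppressMessages(library(mutmapr))
dir.create("results/sim", showWarnings = FALSE, recursive = TRUE)
set.seed(101)

genome <- default_genome()
causal_a <- list(chrom = "chr07", pos = 1600000, ref = "G", alt = "A")
causal_b <- list(chrom = "chr07", pos = 2100000, ref = "C", alt = "T")

line_a <- simulate_mutagenesis(genome, 2000, causal_a, line_id = "pool76",
                               seed = 102)
line_b <- simulate_mutagenesis(genome, 2000, causal_b, line_id = "pool18",
                               seed = 103, avoid = line_a)

# cultivar polymorphisms shared by both parents of every cross
shared <- local({
  chr <- genome$chromosomes
  ci <- sample.int(nrow(chr), 300, replace = TRUE, prob = chr$length)
  data.frame(chrom = chr$name[ci],
             pos = floor(runif(300, 0, chr$length[ci])) + 1,
             ref = sample(c("A", "C", "G", "T"), 300, replace = TRUE),
             alt = NA)
})
shared$alt <- vapply(shared$ref, function(r)
  sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1))

pool_a <- simulate_f2_pool(line_a, genome,
                           f2_pool_spec(76, depth = 20, seed = 104),
                           shared_variants = shared)
pool_b <- simulate_f2_pool(line_b, genome,
                           f2_pool_spec(18, depth = 20, seed = 105),
                           shared_variants = shared)
wt <- simulate_wildtype_pool(shared, depth = 20, seed = 106)

write_variant_vcf(pool_a, "results/sim/pool76.vcf")
write_variant_vcf(pool_b, "results/sim/pool18.vcf")
write_variant_vcf(wt, "results/sim/wildtype.vcf")
saveRDS(list(causal_a = causal_a, causal_b = causal_b),
        "results/sim/truth.rds")

cat(sprintf("pool76: %d records (%d causal/background, %d shared)\n",
            nrow(pool_a), sum(pool_a$source != "shared"),
            sum(pool_a$source == "shared")))
cat(sprintf("pool18: %d records\n", nrow(pool_b)))
cat(sprintf("causal truth: pool76 %s:%d %s>%s, pool18 %s:%d %s>%s\n",
            causal_a$chrom, causal_a$pos, causal_a$ref, causal_a$alt,
            causal_b$chrom, causal_b$pos, causal_b$ref, causal_b$alt))
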