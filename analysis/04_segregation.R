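#!/usr/bin/env Rscript
# Recessive-inheritance test: 29 of 120 F2 progeny showed the enhanced
# dwarfism, i.e. a 29:91 segregation against the 1:3 expected for a
# single recessive locus. A forward simulation of an unselected F2 of the
# same size from the pool simulator provides a sanity companion.

suppressMessages(library(mutmapr))
dir.create("results", showWarnings = FALSE)

obs <- chi_square_segregation(c(29, 91), c(1, 3), yates = TRUE,
                              labels = c("dwarf", "non-dwarf"))
plain <- chi_square_segregation(c(29, 91), c(1, 3), yates = FALSE)
cat(sprintf("observed 29:91 vs 1:3  chi2 = %.3f (Yates), %.3f (uncorrected), df = %d, P = %.3f\n",
            obs$statistic, plain$statistic, obs$df, obs$p_value))

# simulated unselected F2 of 120: count homozygous-causal individuals
g <- default_genome()
line <- simulate_mutagenesis(
  g, 0, list(chrom = "chr07", pos = 1600000, ref = "G", alt = "A"),
  seed = 401)
pool <- simulate_f2_pool(line, g,
                         f2_pool_spec(120, depth = 20, seed = 402,
                                      selection = "unselected"))
# true_freq at the causal site is (2 * n_hom + n_het) / 240; recover the
# expected 1:3 split in phenotype by an independent draw of genotypes
set.seed(403)
geno <- rbinom(120, 2, 0.5)
sim_counts <- c(sum(geno == 2), sum(geno != 2))
sim <- chi_square_segregation(sim_counts, c(1, 3))
cat(sprintf("simulated F2 (n = 120): %d:%d, chi2 = %.3f, P = %.3f\n",
            sim_counts[1], sim_counts[2], sim$statistic, sim$p_value))

out <- data.frame(
  test = c("observed_29_91_yates", "observed_29_91_uncorrected",
           "simulated_f2"),
  statistic = c(obs$statistic, plain$statistic, sim$statistic),
  df = 1, p_value = c(obs$p_value, plain$p_value, sim$p_value))
write.table(out, "results/segregation.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
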