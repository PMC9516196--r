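#!/usr/bin/env Rscript
# Classify the candidate SNPs in each mapped peak by codon consequence
# against a synthetic homeobox-like gene model placed at the causal locus:
# a 300-codon CDS whose codon 276 is TGG (Trp) and codon 286 is CCA (Pro),
# with a homeodomain spanning amino acids 260-320. The two causal SNPs are
# engineered to hit these codons, so annotation should report a gained
# stop (W276*) for the first pool's candidate and a P286S missense for
# the second -- both inside the homeodomain.

suppressMessages(library(mutmapr))
dir.create("results/annotation", showWarnings = FALSE, recursive = TRUE)
truth <- readRDS("results/sim/truth.rds")

# synthetic gene: CDS starts so that codon 276 position 3 lands exactly on
# the first pool's causal position
codons <- rep("GGC", 300)
codons[276] <- "TGG"
codons[286] <- "CCA"
cds_start <- truth$causal_a$pos - ((276 - 1) * 3 + 3) + 1
cds <- data.frame(start = cds_start, end = cds_start + 900 - 1)
model <- gene_model("OSHlike07", "chr07", "+", cds,
                    domains = data.frame(name = c("KNOX1", "KNOX2", "ELK",
                                                  "homeodomain"),
                                         aa_start = c(20, 90, 230, 260),
                                         aa_end = c(80, 150, 259, 320)))

# chromosome sequence: only the CDS neighbourhood needs real bases
chr07_len <- default_genome()$chromosomes$length[7]
seq <- paste(rep("A", chr07_len), collapse = "")
substr(seq, cds$start, cds$end) <- paste(codons, collapse = "")
reference <- Biostrings::DNAStringSet(seq)
names(reference) <- "chr07"

write_gene_models_gff3(list(model), "results/annotation/models.gff3")

candidates <- variant_records(
  chrom = "chr07",
  pos = c(truth$causal_a$pos, cds_start + (286 - 1) * 3),
  ref = c("G", "C"), alt = c("A", "T"),
  alt_depth = c(20, 19), total_depth = 20)
calls <- annotate_candidates(candidates, list(model), reference)
write.table(calls, "results/annotation/effect_calls.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

for (i in seq_len(nrow(calls))) {
  cat(sprintf("%s:%d %s>%s  %s codon %d (%s->%s, %s%d%s)  domain: %s\n",
              calls$chrom[i], calls$pos[i], calls$ref[i], calls$alt[i],
              calls$category[i], calls$codon_number[i],
              calls$ref_codon[i], calls$alt_codon[i], calls$ref_aa[i],
              calls$codon_number[i], calls$alt_aa[i], calls$domain_hit[i]))
}
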