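#!/usr/bin/env Rscript
# Differential-expression co-regulation analysis on constructed tables:
# two single mutants of interacting transcription factors plus their
# double mutant, 20,000-gene universe, planted joint-direction structure
# (see coregulation_profiles()). DEGs are P <= 0.05 and |log2FC| >= 1;
# overlap, direction concordance and the behaviour of the shared
# downregulated genes in the double mutant are then summarised, and the
# co-downregulated genes are clustered (complete linkage, Euclidean).

suppressMessages(library(mutmapr))
dir.create("results/deg", showWarnings = FALSE, recursive = TRUE)

tabs <- simulate_deg_tables(
  deg_sim_spec(20000, coregulation_profiles(), seed = 501))
for (nm in names(tabs)) {
  write_deg_table(tabs[[nm]], sprintf("results/deg/%s_raw.tsv", nm))
}
degs <- lapply(tabs, filter_degs)
ov <- overlap_summary(degs[c("mut_b", "mut_a", "double")])
print(ov)
write.table(ov$sets, "results/deg/overlap_sets.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(ov$pairs, "results/deg/overlap_pairs.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(ov$conditional, "results/deg/overlap_conditional.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

# cluster the genes downregulated in all three mutants on their log2FC
down_all <- Reduce(intersect, lapply(degs, function(d)
  d$gene_id[d$direction == "down"]))
mat <- vapply(tabs, function(t)
  t$log2fc[match(down_all, t$gene_id)], numeric(length(down_all)))
rownames(mat) <- down_all
cl <- cluster_log2fc(mat)
cat(sprintf("\nclustered %d co-downregulated genes; contrasts merge as: %s\n",
            nrow(mat),
            paste(colnames(cl$matrix), collapse = " | ")))
if (requireNamespace("pheatmap", quietly = TRUE)) {
  pdf("results/deg/codown_heatmap.pdf", width = 4, height = 6)
  pheatmap::pheatmap(mat, clustering_method = "complete",
                     clustering_distance_rows = "euclidean",
                     clustering_distance_cols = "euclidean",
                     show_rownames = FALSE)
  dev.off()
}
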