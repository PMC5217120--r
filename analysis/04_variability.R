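#!/usr/bin/env Rscript
# Stage 4: interindividual variability. Spearman correlation of miRNA and
# piRNA expression, hierarchical clustering of samples (average linkage on
# 1 - rho), and the within-compartment variability comparison (Wilcoxon
# rank-sum on the 136 within-cell vs 136 within-exosome pairwise
# correlations).

library(exosmir)

dat <- "results/data"
out <- "results"
tx <- read.table(file.path(dat, "transcripts.tsv"), header = TRUE,
                 sep = "\t", stringsAsFactors = FALSE)
counts <- read_counts_tsv(file.path(dat, "counts.tsv"),
                          file.path(dat, "samples.tsv"))

for (bio in c("miRNA", "piRNA")) {
  keep <- rownames(counts$counts) %in% tx$name[tx$biotype == bio]
  cm <- count_matrix(counts$counts[keep, , drop = FALSE], counts$samples)
  norm <- normalize_counts(cm)
  rho <- spearman_matrix(norm, cm$samples$compartment)
  write.table(unclass(rho), file.path(out, sprintf("spearman_%s.tsv", bio)),
              sep = "\t", quote = FALSE)
  hc <- cluster_samples(rho)
  write_dendrogram_newick(hc, file.path(out, sprintf("dendrogram_%s.nwk", bio)))
  cut2 <- cutree(hc, 2)
  pure <- all(tapply(cm$samples$compartment, cut2,
                     function(x) length(unique(x)) == 1))
  v <- compare_within_compartment_variability(rho)
  message(sprintf(
    "%s: mean within-cell rho %.3f vs within-exosome %.3f (Wilcoxon p = %.2e); two-cluster cut %s by compartment",
    bio, v$mean_cell, v$mean_exosome, v$p,
    if (pure) "splits exactly" else "does not split exactly"))
}
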