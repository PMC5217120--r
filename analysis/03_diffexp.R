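#!/usr/bin/env Rscript
# Stage 3: differential expression between compartments at three levels
# (mature miRNA, miRNA cluster, piRNA) with the simplified NB engine at 1%
# FDR, plus a 10%-depth downsampling robustness check.

library(exosmir)

dat <- "results/data"
out <- "results"
ann <- read_mirna_annotation(file.path(dat, "annotation.gff3"))
tx <- read.table(file.path(dat, "transcripts.tsv"), header = TRUE,
                 sep = "\t", stringsAsFactors = FALSE)
counts <- read_counts_tsv(file.path(dat, "counts.tsv"),
                          file.path(dat, "samples.tsv"))
seed <- as.integer(Sys.getenv("EXOSMIR_SEED", "1"))

subset_bio <- function(cm, b) {
  keep <- rownames(cm$counts) %in% tx$name[tx$biotype == b]
  count_matrix(cm$counts[keep, , drop = FALSE], cm$samples)
}
mirna <- subset_bio(counts, "miRNA")
pirna <- subset_bio(counts, "piRNA")
cl <- build_clusters(ann)
cluster_counts <- aggregate_cluster_counts(mirna, cl)

res <- list(mature = nb_differential_test(mirna),
            cluster = nb_differential_test(cluster_counts),
            pirna = nb_differential_test(pirna))
for (lvl in names(res)) {
  write.table(res[[lvl]], file.path(out, sprintf("diffexp_%s.tsv", lvl)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  n_sig <- sum(res[[lvl]]$padj < 0.01, na.rm = TRUE)
  message(sprintf("%s level: %d/%d significant at 1%% FDR (%d up in exosomes)",
                  lvl, n_sig, nrow(res[[lvl]]),
                  sum(res[[lvl]]$padj < 0.01 & res[[lvl]]$log2fc > 0,
                      na.rm = TRUE)))
}
write.table(ma_table(res$mature), file.path(out, "ma_mature.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# depth robustness: binomially downsample to 10% and compare the 1%-FDR call
# sets at the mature level
down <- downsample_counts(mirna, 0.1, seed = seed)
res_d <- nb_differential_test(down)
full_sig <- res$mature$transcript[res$mature$padj < 0.01 & !is.na(res$mature$padj)]
down_sig <- res_d$transcript[res_d$padj < 0.01 & !is.na(res_d$padj)]
message(sprintf(
  "downsampling to 10%%: %d/%d full-depth calls retained; %d new calls",
  length(intersect(full_sig, down_sig)), length(full_sig),
  length(setdiff(down_sig, full_sig))))
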