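#!/usr/bin/env Rscript
# Stage 2: build miRNA clusters under the 10-kb proximity rule and compare
# the RNA-biotype composition of cells and exosomes (paired t-tests,
# Bonferroni over the six classes).

library(exosmir)

dat <- "results/data"
out <- "results"
ann <- read_mirna_annotation(file.path(dat, "annotation.gff3"))
tx <- read.table(file.path(dat, "transcripts.tsv"), header = TRUE,
                 sep = "\t", stringsAsFactors = FALSE)
counts <- read_counts_tsv(file.path(dat, "counts.tsv"),
                          file.path(dat, "samples.tsv"))

cl <- build_clusters(ann, max_gap = 10000)
write_cluster_table(cl, ann, file.path(out, "clusters.tsv"))
sizes <- lengths(cl$clusters)
message(sprintf("clusters: %d total; %d singletons; largest has %d hairpins",
                length(sizes), sum(sizes == 1), max(sizes)))

biotype <- setNames(tx$biotype, tx$name)
prop <- biotype_proportions(counts, biotype)
tests <- compare_compositions(prop)
write.table(tests, file.path(out, "composition_tests.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
sig <- tests$class[!is.na(tests$p_bonferroni) & tests$p_bonferroni < 0.05]
message(sprintf("composition: %d/6 classes differ after Bonferroni (%s)",
                length(sig), paste(sig, collapse = ", ")))
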