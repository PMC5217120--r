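#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study — a 17-member three-generation family
# (4 grandparents, 2 parents, 11 children) with biallelic genotypes, a
# small-RNA annotation carrying one tightly spaced exported miRNA cluster,
# paired cell/exosome NB counts for all 17 individuals, and hairpin-local
# alignments with nontemplated tails. All downstream stages read these files.

library(exosmir)

seed <- as.integer(Sys.getenv("EXOSMIR_SEED", "1"))
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = seed)
pg <- simulate_pedigree_genotypes(cfg)
ann <- simulate_annotation(cfg, avoid = pg$genotypes$markers)
cnt <- simulate_counts(pg$pedigree, ann, cfg, pg$truth)

write_genotypes_vcf(pg$genotypes, file.path(out, "genotypes.vcf"))
write_genotypes_tsv(pg$genotypes, file.path(out, "genotypes.tsv"))
write_mirna_annotation(ann, file.path(out, "annotation.gff3"))
write.table(ann$transcripts, file.path(out, "transcripts.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(pg$pedigree, file.path(out, "pedigree.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_counts_tsv(cnt$counts, file.path(out, "counts.tsv"),
                 file.path(out, "samples.tsv"))
aln <- simulate_hairpin_alignments(cfg)
write_sam(aln$sam, file.path(out, "hairpin_alignments.sam"))
write_fastq(aln$unmapped, file.path(out, "unmapped.fastq"))
write_truth_json(cnt$truth[c("lfc", "eqtl")], file.path(out, "truth.json"))

message(sprintf(
  "simulated %d individuals, %d markers, %d transcripts, %d aligned reads (seed %d)",
  nrow(pg$pedigree), nrow(pg$genotypes$markers), nrow(ann$transcripts),
  cfg$n_aln_reads, seed))
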