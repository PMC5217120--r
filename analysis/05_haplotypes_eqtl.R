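#!/usr/bin/env Rscript
# Stage 5: pedigree haplotypes and cis-eQTL mapping. Mendelian filtering,
# grandparent-anchored phasing, transmission inference, haplotype blocks,
# the two-haplotype linear model per compartment (median normalized
# expression >= 10; multi-locus and variant-overlapping transcripts
# excluded), cross-compartment effect correlation, the 20%-FDR shared-eQTL
# intersection, and the nongenetic-confounder checks.

library(exosmir)

dat <- "results/data"
out <- "results"
gt <- read_genotypes_vcf(file.path(dat, "genotypes.vcf"))
ped <- read.table(file.path(dat, "pedigree.tsv"), header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE)
tx <- read.table(file.path(dat, "transcripts.tsv"), header = TRUE,
                 sep = "\t", stringsAsFactors = FALSE)
rownames(tx) <- tx$name
ann <- read_mirna_annotation(file.path(dat, "annotation.gff3"))
ann$transcripts <- tx
counts <- read_counts_tsv(file.path(dat, "counts.tsv"),
                          file.path(dat, "samples.tsv"))
seed <- as.integer(Sys.getenv("EXOSMIR_SEED", "1"))
chrom_len <- sim_config(seed = seed)$chrom_length

mf <- mendelian_filter(gt, ped)
message(sprintf("Mendelian filter: dropped %d of %d markers",
                nrow(mf$report), nrow(gt$markers)))
ph <- phase_parents(mf$genotypes, ped)
tr <- infer_transmissions(mf$genotypes, ph, ped)
chroms <- unique(mf$genotypes$markers$chrom)
bl <- segment_blocks(tr, setNames(rep(chrom_len, length(chroms)), chroms))
write_blocks(bl, file.path(out, "blocks.bed"), file.path(out, "block_codes.tsv"))
message(sprintf("haplotype blocks: %d across %d chromosomes",
                nrow(bl$blocks), length(chroms)))

variants <- mf$genotypes$markers[, c("chrom", "pos")]
fits <- lapply(c(cell = "cell", exosome = "exosome"), function(comp)
  map_eqtls(counts, bl, ann, variants, comp, ped,
            biotypes = c("miRNA", "piRNA")))
for (comp in names(fits))
  write.table(fits[[comp]], file.path(out, sprintf("eqtl_%s.tsv", comp)),
              sep = "\t", quote = FALSE, row.names = FALSE)

corr <- effect_correlation(fits$cell, fits$exosome)
shared <- shared_eqtls(fits$cell, fits$exosome, fdr = 0.20)
write.table(shared, file.path(out, "shared_eqtls.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf(
  "eQTL: %d tested in cells, %d in exosomes; beta_p correlation r = %.2f; %d shared at 20%% FDR (%s)",
  nrow(fits$cell), nrow(fits$exosome), corr$r[1], nrow(shared),
  paste(shared$transcript, collapse = ", ")))

# confounder checks for the shared candidates: sex association, genome-wide
# association ranking of their blocks, and the k-mer mapping-bias test
if (nrow(shared)) {
  norm <- normalize_counts(count_matrix(
    counts$counts[, counts$samples$compartment == "cell"],
    counts$samples[counts$samples$compartment == "cell", ]))
  children <- ped$id[ped$generation == 3]
  child_cols <- counts$samples$sample[counts$samples$individual %in% children &
                                        counts$samples$compartment == "cell"]
  norm_kids <- norm[, child_cols]
  colnames(norm_kids) <- counts$samples$individual[
    match(child_cols, counts$samples$sample)]
  rk <- rank_haplotypes_by_associations(norm_kids, bl)
  write.table(rk, file.path(out, "haplotype_ranking.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  unmapped <- read_fastq_seqs(file.path(dat, "unmapped.fastq"))
  for (t in shared$transcript) {
    f <- fits$cell[fits$cell$transcript == t, ]
    sex <- sex_confound_check(bl, f$block, ped)
    rank_here <- rk$rank[rk$block == f$block]
    # per-child unmapped read sets (one simulated library per child)
    cfg <- sim_config(seed = seed)
    reads <- setNames(lapply(seq_along(children), function(i)
      simulate_hairpin_alignments(cfg, seed_offset = 20L + i)$unmapped),
      children)
    totals <- setNames(rep(cfg$n_aln_reads + cfg$n_unmapped_reads,
                           length(children)), children)
    qc <- kmer_bias_check(reads, totals, bl$paternal[f$block, ], f$beta_p)
    # contamination rates are equal across children here, so nominal hits
    # should stay near the 5% false-positive expectation
    message(sprintf(
      "  %s: sex-association p = %s; block ranked %d/%d genome-wide; k-mer QC %s (%d/%d k-mers at nominal p <= 0.05; ~%.1f expected by chance)",
      t, format(sex$p, digits = 2), rank_here, nrow(rk), qc$verdict,
      length(qc$offending), qc$n_kmers_tested, 0.05 * qc$n_kmers_tested))
  }
}
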